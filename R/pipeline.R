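#' Default pipeline configuration
#'
#' Returns a complete, validated configuration list for [run_pipeline()].
#' The `"task1-like"` preset emulates the study design of a cap-assembly
#' mutagenesis screen: a wild type, four-fold heptad-site mutants
#' (a/d-sites with a 93% current reduction, f-sites with 20%), seven
#' strongly trafficking-deficient single cap mutants, and a set of
#' EIP-region mutants with gating or mixed defects; the structural stage
#' models the cap region as a synthetic dimer with planted inter-subunit
#' contacts among the hit residues.  The `"null"` preset has no planted
#' effects and no planted contacts.
#'
#' @param preset `"task1-like"` or `"null"`.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param outdir Output directory.
#' @return Named configuration list.
#' @export
default_config <- function(preset = c("task1-like", "null"), seed = 1L,
                           outdir = "k2pcap-run") {
  preset <- match.arg(preset)
  linker <- read_fasta_sequences(
    system.file("extdata", "task1_m1p1.fasta", package = "k2pcap"))[[1L]]
  cap_from <- 45L; cap_to <- 77L
  cap_res <- bio3d::aa123(strsplit(substr(linker, cap_from, cap_to), "")[[1L]])
  if (preset == "task1-like") {
    constructs <- rbind(
      data.frame(construct_id = "WT", rel_current = 1, rel_surface = 1),
      data.frame(construct_id = c("4x-a", "4x-d"),
                 rel_current = 0.07, rel_surface = 0.07),
      data.frame(construct_id = "4x-f", rel_current = 0.80, rel_surface = 1),
      data.frame(construct_id = c("L48A", "Y52A", "N53A", "L54A", "S55A",
                                  "Y59A", "L62A"),
                 rel_current = 0.07, rel_surface = 0.07),
      data.frame(construct_id = "Q56A", rel_current = 1, rel_surface = 1),
      data.frame(construct_id = c("K70A", "P71A", "K73A"),
                 rel_current = 0.15, rel_surface = 1),
      data.frame(construct_id = "H72A", rel_current = 0.25,
                 rel_surface = 0.25),
      data.frame(construct_id = c("A74V", "Q77A"), rel_current = 0.15,
                 rel_surface = 0.5))
    pairs <- data.frame(res_i = c(52, 53, 54, 59, 62),
                        res_j = c(55, 53, 54, 59, 59),
                        target = c(5.0, 4.6, 4.8, 5.2, 5.5))
  } else {
    constructs <- data.frame(
      construct_id = c("WT", paste0("M", seq_len(6))),
      rel_current = 1, rel_surface = 1)
    pairs <- NULL
  }
  list(
    preset = preset, seed = as.integer(seed), outdir = outdir,
    coils = list(window = 28L, matrix_id = "MTIDK", weighting = 2.5,
                 anchor = 38L, fasta = NULL),
    screen = list(constructs = constructs, n_oocytes = 20L, cv = 0.3,
                  n_batches = 2L, reference = "WT", per_batch = TRUE),
    cap = list(residues = cap_res, start_resno = cap_from, pairs = pairs,
               sigma = 0.25, n_frames = 150L),
    contacts = list(cutoff = 6.0),
    thresholds = list(current = 0.3, conductivity_band = c(0.5, 2),
                      p = 0.001))
}

#' Validate a pipeline configuration
#'
#' Checks every stage parameter before anything runs; errors name the
#' offending field.
#'
#' @param config Configuration list (see [default_config()]).
#' @return `config`, invisibly, on success.
#' @export
validate_config <- function(config) {
  fail <- function(...) stop("invalid config: ", ..., call. = FALSE)
  need <- c("seed", "outdir", "coils", "screen", "cap", "contacts",
            "thresholds")
  miss <- setdiff(need, names(config))
  if (length(miss)) fail("missing field(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(config$seed) || config$seed != round(config$seed))
    fail("seed must be an integer")
  if (!config$coils$window %in% c(14L, 21L, 28L))
    fail("coils$window must be 14, 21 or 28")
  if (!config$coils$weighting %in% c(1, 2.5))
    fail("coils$weighting must be 1 or 2.5")
  if (!is.numeric(config$contacts$cutoff) || config$contacts$cutoff <= 0)
    fail("contacts$cutoff must be > 0")
  if (config$screen$n_oocytes < 2) fail("screen$n_oocytes must be >= 2")
  if (config$screen$cv < 0) fail("screen$cv must be >= 0")
  if (config$cap$sigma < 0) fail("cap$sigma must be >= 0")
  if (config$cap$n_frames < 1) fail("cap$n_frames must be >= 1")
  thr <- config$thresholds
  if (thr$current <= 0 || thr$p <= 0 || thr$p > 1)
    fail("thresholds$current and thresholds$p must be positive (p <= 1)")
  if (length(thr$conductivity_band) != 2L ||
      thr$conductivity_band[1] >= thr$conductivity_band[2])
    fail("thresholds$conductivity_band must be an increasing interval")
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#'
#' Configurations round-trip through YAML; the construct and planted-pair
#' tables are stored as column lists and restored to data frames.
#'
#' @param path YAML file path.
#' @param config Configuration list (for `write_config`).
#' @return `read_config`: the configuration list; `write_config`: `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  config <- yaml::read_yaml(path)
  if (!is.null(config$screen$constructs))
    config$screen$constructs <- as.data.frame(config$screen$constructs)
  if (!is.null(config$cap$pairs) && length(config$cap$pairs))
    config$cap$pairs <- as.data.frame(config$cap$pairs)
  else config$cap$pairs <- NULL
  validate_config(config)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Map construct ids like "L48A" to mutated residue positions; multi-site
# constructs (anything not matching one-letter + number + one-letter)
# return NA.
construct_residue <- function(construct_id) {
  m <- regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", construct_id)
  vapply(regmatches(construct_id, m), function(g)
    if (length(g) == 4L) as.integer(g[3L]) else NA_integer_, integer(1))
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: **simulate** (screen table, ground truth,
#' synthetic cap trajectory), **coils** (per-position coiled-coil profile
#' of the bundled M1-P1 linker or a user FASTA), **screen** (per-construct
#' summaries and the derived trafficking-deficient hit list), **contacts**
#' (contact matrix of the trajectory with interaction calls) and
#' **concordance** (scoring of the model against the hit list).  Every
#' output file is recorded in a manifest with its MD5 hash; re-running with
#' an identical configuration reproduces identical hashes.  Progress is
#' logged to `stderr` via [message()].
#'
#' @param config Configuration list from [default_config()] /
#'   [read_config()]; validated before any stage runs.
#' @return Data frame manifest (`stage`, `file`, `md5`), invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  emit <- function(stage, name, writer) {
    path <- file.path(config$outdir, name)
    writer(path)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = name, md5 = unname(tools::md5sum(path)))
    path
  }
  stage <- function(name, code) {
    message("[k2pcap] stage ", name, " ...")
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- simulate -------------------------------------------------------------
  scr <- NULL; traj <- NULL
  stage("simulate", {
    scr <- simulate_screen(config$screen$constructs,
                            n_oocytes = config$screen$n_oocytes,
                            cv = config$screen$cv,
                            n_batches = config$screen$n_batches,
                            reference_id = config$screen$reference,
                            seed = config$seed)
    emit("simulate", "screen.csv", function(p)
      write.csv(scr, p, row.names = FALSE))
    emit("simulate", "truth.yaml", function(p)
      yaml::write_yaml(attr(scr, "truth"), p))
    cap <- make_toy_cap(config$cap$residues, config$cap$pairs,
                        start_resno = config$cap$start_resno,
                        seed = config$seed + 1L)
    traj <- jitter_trajectory(cap, config$cap$sigma, config$cap$n_frames,
                               seed = config$seed + 2L)
    emit("simulate", "cap_trajectory.pdb", function(p)
      write_structure_pdb(traj, p))
  })

  # -- coils ----------------------------------------------------------------
  stage("coils", {
    fasta <- config$coils$fasta
    if (is.null(fasta))
      fasta <- system.file("extdata", "task1_m1p1.fasta", package = "k2pcap")
    seqs <- read_fasta_sequences(fasta)
    prof <- coils_profile(seqs[[1L]], config$coils$window,
                          config$coils$matrix_id, config$coils$weighting,
                          anchor = config$coils$anchor)
    emit("coils", "coils_profile.csv", function(p)
      write.csv(prof, p, row.names = FALSE))
  })

  # -- screen ---------------------------------------------------------------
  hits <- NULL
  stage("screen", {
    thr <- config$thresholds
    summ <- summarize_screen(scr, config$screen$reference,
                             per_batch = config$screen$per_batch,
                             current_threshold = thr$current,
                             conductivity_band = thr$conductivity_band,
                             p_threshold = thr$p)
    emit("screen", "screen_summary.csv", function(p)
      write.csv(summ, p, row.names = FALSE))
    hit_rows <- summ$is_hit & summ$mechanism == "trafficking_deficient"
    hits <- sort(unique(stats::na.omit(
      construct_residue(summ$construct_id[hit_rows]))))
    emit("screen", "hits.txt", function(p)
      writeLines(as.character(hits), p))
  })

  # -- contacts -------------------------------------------------------------
  cm <- NULL
  stage("contacts", {
    cap_resno <- sort(unique(traj$atoms$resno))
    cm <- call_interactions(contact_matrix(traj, cap_resno),
                             config$contacts$cutoff)
    emit("contacts", "contacts.csv", function(p) write_contact_csv(cm, p))
    emit("contacts", "contacts_table.csv", function(p)
      write_contact_csv(cm, p, layout = "square"))
  })

  # -- concordance ----------------------------------------------------------
  stage("concordance", {
    if (!length(hits)) {
      message("[k2pcap]   no trafficking-deficient hits; writing empty report")
      emit("concordance", "concordance.csv", function(p)
        write.csv(data.frame(), p, row.names = FALSE))
    } else {
      rep1 <- score_model(cm, hits, model_id = config$preset)
      emit("concordance", "concordance.csv", function(p)
        write.csv(rank_models(list(rep1)), p, row.names = FALSE))
    }
  })

  manifest <- do.call(rbind, manifest)
  emit2 <- file.path(config$outdir, "manifest.csv")
  write.csv(manifest, emit2, row.names = FALSE)
  message("[k2pcap] done: ", nrow(manifest), " outputs in ", config$outdir)
  invisible(manifest)
}

# ---------------------------------------------------------------------------
# Minimal command-line front end (see exec/k2pcap): subcommands dispatching
# to the exported functions.  Flag parsing is deliberately tiny
# (--key value / --flag), so the CLI works without extra dependencies.

.cli_args <- function(argv) {
  out <- list(); i <- 1L
  while (i <= length(argv)) {
    a <- argv[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(argv) && !startsWith(argv[[i + 1L]], "--")) {
        out[[key]] <- argv[[i + 1L]]; i <- i + 2L
      } else { out[[key]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `coils`, `screen`, `contacts`, `concordance`,
#' `simulate` and `reproduce` to the corresponding package functions; the
#' installed `exec/k2pcap` script forwards `commandArgs()` here.  Outputs go
#' to files, logs to `stderr`.
#'
#' @param argv Character vector of command-line arguments (subcommand
#'   first).
#' @return Invisibly, the result of the dispatched operation.
#' @export
k2pcap_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: k2pcap <coils|screen|contacts|concordance|simulate|reproduce>",
    "[--key value ...]",
    " coils:       --fasta F [--window 28] [--matrix MTIDK]",
    "              [--weighting 2.5] [--register-anchor N] --out CSV",
    " screen:      --csv F [--reference WT] [--no-per-batch] --out CSV",
    " contacts:    --pdb F --residues 48,52,... [--cutoff 6] --out CSV",
    " concordance: --contacts CSV --hits F --out CSV",
    " simulate:    [--preset task1-like|null] [--seed 1] --outdir DIR",
    " reproduce:   [--config YAML] [--preset ...] [--seed 1] --outdir DIR",
    sep = "\n")
  if (!length(argv)) { cat(usage, "\n"); return(invisible(NULL)) }
  cmd <- argv[[1L]]
  a <- .cli_args(argv[-1L])
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  res <- switch(cmd,
    coils = {
      seqs <- read_fasta_sequences(a$fasta)
      anchor <- if (is.null(a[["register-anchor"]])) NULL
                else as.integer(a[["register-anchor"]])
      prof <- coils_profile(seqs[[1L]], num(a$window, 28),
                            if (is.null(a$matrix)) "MTIDK" else a$matrix,
                            num(a$weighting, 2.5), anchor = anchor)
      write.csv(prof, a$out, row.names = FALSE)
      prof
    },
    screen = {
      meas <- read_screen_csv(a$csv)
      summ <- summarize_screen(
        meas, if (is.null(a$reference)) "WT" else a$reference,
        per_batch = is.null(a[["no-per-batch"]]))
      write.csv(summ, a$out, row.names = FALSE)
      summ
    },
    contacts = {
      model <- read_structure_pdb(a$pdb)
      res <- as.integer(strsplit(a$residues, ",")[[1L]])
      cm <- call_interactions(contact_matrix(model, res), num(a$cutoff, 6))
      write_contact_csv(cm, a$out)
      cm
    },
    concordance = {
      cm <- read_contact_csv(a$contacts)
      rep1 <- score_model(cm, read_hit_list(a$hits))
      write.csv(rank_models(list(rep1)), a$out, row.names = FALSE)
      rep1
    },
    simulate = ,
    reproduce = {
      config <- if (!is.null(a$config)) read_config(a$config)
        else default_config(
          preset = if (is.null(a$preset)) "task1-like" else a$preset,
          seed = as.integer(num(a$seed, 1)),
          outdir = if (is.null(a$outdir)) "k2pcap-run" else a$outdir)
      if (!is.null(a$outdir)) config$outdir <- a$outdir
      if (!is.null(a$seed)) config$seed <- as.integer(num(a$seed, 1))
      run_pipeline(config)
    },
    stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE))
  invisible(res)
}
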