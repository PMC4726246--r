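#' Score a structural model against a mutagenesis hit list
#'
#' Counts the inter-subunit interaction calls of a contact matrix whose two
#' residues both belong to the hit list, and reports which hits are covered
#' (touched by at least one such call).  Homotypic diagonal calls (residue i
#' with i of the opposing subunit) count as one interaction covering one
#' hit.  Intra-subunit calls are tallied separately but excluded from the
#' score: they carry no information about dimer assembly.  The mean
#' inter-subunit distance over **all** hit pairs (called or not) is reported
#' as the tie-breaking statistic used by [rank_models()].
#'
#' @param cm A `cap_contact_matrix`; if it has no `call` column yet,
#'   [call_interactions()] is applied with `cutoff`.
#' @param hits Hit residues: integer positions, labels like `"L48"`, or a
#'   data frame with a `pos` column.  Every hit must be present in the
#'   matrix residue set.
#' @param model_id Label for the model (default `"model"`).
#' @param cutoff Cutoff used when `cm` carries no calls (default 6.0).
#' @return One-row data frame of class `concordance_report`:
#'   `model_id`, `n_inter_calls`, `n_intra_calls`, `n_hits`,
#'   `n_hits_covered`, `coverage`, `mean_hit_distance`; the covered hit
#'   positions are in attribute `covered`.
#' @export
score_model <- function(cm, hits, model_id = "model", cutoff = 6.0) {
  if (is.null(cm$call)) cm <- call_interactions(cm, cutoff)
  hit_pos <- if (is.data.frame(hits)) hits$pos else parse_residue(hits)$pos
  hit_pos <- sort(unique(as.integer(hit_pos)))
  if (!length(hit_pos)) stop("hit list is empty")
  res <- attr(cm, "residues")
  if (is.null(res)) res <- sort(unique(c(cm$res_i, cm$res_j)))
  missing <- setdiff(hit_pos, res)
  if (length(missing))
    stop("hit residue(s) absent from the contact matrix: ",
         paste(missing, collapse = ", "))

  both_hits <- cm$res_i %in% hit_pos & cm$res_j %in% hit_pos
  inter <- cm$relationship == "inter"
  called <- inter & both_hits & cm$call
  covered <- sort(unique(c(cm$res_i[called], cm$res_j[called])))
  out <- data.frame(
    model_id = model_id,
    n_inter_calls = sum(called),
    n_intra_calls = sum(!inter & both_hits & cm$call),
    n_hits = length(hit_pos),
    n_hits_covered = length(covered),
    coverage = length(covered) / length(hit_pos),
    mean_hit_distance = if (any(inter & both_hits))
      mean(cm$mean[inter & both_hits]) else NA_real_)
  attr(out, "covered") <- covered
  class(out) <- c("concordance_report", "data.frame")
  out
}

#' Rank concordance reports
#'
#' Orders models by descending inter-subunit call count; ties are broken by
#' ascending mean hit-pair distance (a model whose hit residues sit closer
#' across the interface is the better explanation of the mutagenesis data --
#' a heuristic, not a significance statement), and full ties keep input
#' order (stable sort).
#'
#' @param reports A list of [score_model()] outputs, or a data frame of
#'   stacked reports.
#' @return Data frame of the reports in rank order with a `rank` column.
#' @export
rank_models <- function(reports) {
  if (is.data.frame(reports)) df <- as.data.frame(reports)
  else df <- do.call(rbind, lapply(reports, as.data.frame))
  if (is.null(df) || !nrow(df)) stop("no reports to rank")
  key2 <- ifelse(is.na(df$mean_hit_distance), Inf, df$mean_hit_distance)
  o <- order(-df$n_inter_calls, key2)  # order() is stable for full ties
  out <- df[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read a hit list file
#'
#' One residue per line, either `"L48"`-style labels or bare positions;
#' blank lines and `#` comments are ignored.
#'
#' @param path Text file path.
#' @return Data frame with columns `aa`, `pos` (see [parse_residue()]).
#' @export
read_hit_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("hit list file is empty: ", path)
  if (all(grepl("^[0-9]+$", x))) parse_residue(as.integer(x))
  else parse_residue(x)
}
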