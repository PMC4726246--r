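>TASK1_human_Nterm residues 1-100 of human TASK-1 (KCNK3, NM_002246); M1-P1 linker spans ~27-95
MKRQNVRTLALIVCTFTYLLVGAAVFDALESEPELIERQRLELRQQELRARYNLSQGGYE
ELERVVLRLKPHKAGVQWRFAGSFYFAITVITTIGYGHAA
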