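# Hand-planted toy reference records with known residues at known positions,
# so expected values can be read off the construction.

# ase1-like: 731 residues, all 'A' except planted positions
toy_ase1 <- function() {
  s <- strrep("A", 731)
  substr(s, 1, 1) <- "M"
  substr(s, 114, 114) <- "P"
  substr(s, 115, 115) <- "L"
  substr(s, 116, 116) <- "I"
  substr(s, 117, 117) <- "Q"
  substr(s, 494, 494) <- "N"
  new_ref_gene("ase1", "SPTOY001", "protein", s)
}

# rpb1-like: 100-residue amino-terminal region then 29 YSPTSPS repeats
toy_rpb1 <- function() {
  prefix <- paste0("M", strrep("G", 99))
  s <- paste0(prefix, strrep("YSPTSPS", 29))
  substr(s, 2, 2) <- "S"
  new_ref_gene("rpb1", "SPTOY002", "protein", s,
               ctd = list(unit = "YSPTSPS", n_repeats = 29L,
                          region_start = 101L))
}

# histone-like: named positions are shifted by the removed initiator Met
toy_hht1 <- function() {
  new_ref_gene("hht1", "SPTOY003", "protein",
               paste0("MARTKQTARKSTGGKAPRKQLA", strrep("K", 100)),
               histone = TRUE)
}

# RNA gene: transcript coordinates, DNA letters
toy_rna <- function() {
  new_ref_gene("prl35", "SPTOY004", "rna",
               paste0("GATTACA", strrep("ACGT", 30)))
}

# two transcripts: the second is shorter
toy_two_transcripts <- function() {
  new_ref_gene("zas1", "SPTOY005", "protein",
               c(paste0("M", strrep("E", 199)), paste0("M", strrep("R", 99))))
}

toy_refdb <- function() {
  new_refdb(list(toy_ase1(), toy_rpb1(), toy_hht1(), toy_rna(),
                 toy_two_transcripts()))
}
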