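# Independent brute-force oracle for full-length spacer matching:
# exhaustive Hamming scan over all positions and both strands.
brute_match <- function(spacer, phage, min_identity = 0.80) {
  L <- nchar(spacer)
  max_mm <- floor((1 - min_identity) * L + 1e-9)
  out <- list()
  pv <- utf8ToInt(phage)
  for (strand in c("+", "-")) {
    sp <- if (strand == "+") spacer else revcomp(spacer)
    sv <- utf8ToInt(sp)
    for (p in 0:(nchar(phage) - L)) {
      mm <- sum(pv[(p + 1):(p + L)] != sv)
      if (mm <= max_mm) {
        out[[length(out) + 1]] <- data.frame(
          start = p, strand = strand, mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), , drop = FALSE]
}
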