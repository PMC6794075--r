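# Independent brute-force dip oracle for small n: for every modal split,
# the minimal band half-width from exhaustive chord enumeration (all
# i1 < j < i2 triples), never using incremental hulls.
bruteDip <- function(x) {
  x <- sort(x)
  ux <- unique(x)
  F <- vapply(ux, function(v) mean(x <= v), numeric(1))
  Fm <- vapply(ux, function(v) mean(x < v), numeric(1))
  w <- F - Fm
  m <- length(ux)
  chordMax <- function(idx, yh, ya) {
    best <- 0
    if (length(idx) >= 3) {
      for (a in 1:(length(idx) - 2)) for (b in (a + 2):length(idx)) {
        i1 <- idx[a]; i2 <- idx[b]
        for (jj in idx[idx > i1 & idx < i2]) {
          line <- yh[i1] + (yh[i2] - yh[i1]) * (ux[jj] - ux[i1]) /
            (ux[i2] - ux[i1])
          best <- max(best, ya[jj] - line)
        }
      }
    }
    best
  }
  dSplit <- function(conv, conc) {
    max(if (length(conv)) max(w[conv]) else 0,
        if (length(conc)) max(w[conc]) else 0,
        chordMax(conv, Fm, F),      # convex side: F pokes above chords
        local({                     # concave side: chords of F above F^-
          best <- 0
          idx <- conc
          if (length(idx) >= 3) {
            for (a in 1:(length(idx) - 2)) for (b in (a + 2):length(idx)) {
              i1 <- idx[a]; i2 <- idx[b]
              for (jj in idx[idx > i1 & idx < i2]) {
                line <- F[i1] + (F[i2] - F[i1]) * (ux[jj] - ux[i1]) /
                  (ux[i2] - ux[i1])
                best <- max(best, line - Fm[jj])
              }
            }
          }
          best
        }))
  }
  best <- Inf
  for (k in 0:m) {
    best <- min(best, dSplit(seq_len(k),
                             if (k < m) (k + 1):m else integer()))
  }
  for (j in 1:m) {
    best <- min(best, dSplit(seq_len(j - 1),
                             if (j < m) (j + 1):m else integer()))
  }
  best / 2
}
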