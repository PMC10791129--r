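# Shared fixtures: small, fast phantom specs used across test files.

smallSpec <- function(seed = 1L, ...) {
  # quarter-scale phantom with density-matched Cx43 puncta
  args <- list(shape = c(24, 64, 64), nCells = 4L, nucleusRadius = 1.5,
               cx43Count = 30L, dermisMargin = 3L, cornifiedMargin = 3L,
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantomSpec, args)
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# independent brute-force colocalization counter (triple loop over voxels)
bruteForceCounts <- function(pgp, wga, cx43, box = NULL) {
  if (!is.null(box)) {
    pgp <- pgp[box$z[1]:box$z[2], box$y[1]:box$y[2], box$x[1]:box$x[2],
               drop = FALSE]
    wga <- wga[box$z[1]:box$z[2], box$y[1]:box$y[2], box$x[1]:box$x[2],
               drop = FALSE]
    cx43 <- cx43[box$z[1]:box$z[2], box$y[1]:box$y[2], box$x[1]:box$x[2],
                 drop = FALSE]
  }
  d <- dim(pgp)
  nPgp <- 0L; nPgpWga <- 0L; nTriple <- 0L
  for (z in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      for (x in seq_len(d[3])) {
        if (pgp[z, y, x]) {
          nPgp <- nPgp + 1L
          if (wga[z, y, x]) {
            nPgpWga <- nPgpWga + 1L
            if (cx43[z, y, x]) nTriple <- nTriple + 1L
          }
        }
      }
    }
  }
  list(nPgp = nPgp, nPgpWga = nPgpWga, nPgpCx43Wga = nTriple)
}
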