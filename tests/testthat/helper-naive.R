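# Independent plain-R reference implementations used as oracles. These are
# deliberately written from scratch (own direction table, own decoding and
# counting) and never call into the package's geometry or engine, so that
# agreement is a genuine cross-check.

.naiveSteps <- list(
  R  = c(1L, 0L),  RU = c(0L, 1L),  LU = c(-1L, 1L),
  L  = c(-1L, 0L), LD = c(0L, -1L), RD = c(1L, -1L)
)

naiveDecode <- function(symbols) {
  n <- length(symbols) + 1L
  xy <- matrix(0L, nrow = n, ncol = 2)
  for (i in seq_along(symbols)) {
    xy[i + 1L, ] <- xy[i, ] + .naiveSteps[[symbols[i]]]
  }
  xy
}

naiveIsSAW <- function(xy) {
  nrow(unique(xy)) == nrow(xy)
}

# -1 per H-H pair with sequence separation > 1 at unit lattice distance
naiveEnergy <- function(resChars, xy) {
  n <- length(resChars)
  e <- 0L
  for (i in seq_len(n - 2L)) {
    if (resChars[i] != "H") next
    for (j in (i + 2L):n) {
      if (resChars[j] != "H") next
      d <- xy[j, ] - xy[i, ]
      for (s in .naiveSteps) {
        if (d[1] == s[1] && d[2] == s[2]) {
          e <- e - 1L
          break
        }
      }
    }
  }
  e
}

naiveFitness <- function(resChars, xy, penalty) {
  key <- paste(xy[, 1], xy[, 2])
  coll <- sum(choose(table(key), 2))
  naiveEnergy(resChars, xy) + penalty * coll
}

# exact minimum energy by full recursion over all 6^(n-1) fold strings,
# keeping only self-avoiding walks (no symmetry shortcuts)
naiveMinEnergy <- function(residues) {
  resChars <- strsplit(residues, "")[[1]]
  n <- length(resChars)
  if (n == 1L) return(0L)
  syms <- names(.naiveSteps)
  best <- 0L
  rec <- function(xy) {
    k <- nrow(xy)
    if (k == n) {
      e <- naiveEnergy(resChars, xy)
      if (e < best) best <<- e
      return()
    }
    for (s in syms) {
      nxt <- xy[k, ] + .naiveSteps[[s]]
      clash <- any(xy[, 1] == nxt[1] & xy[, 2] == nxt[2])
      if (!clash) rec(rbind(xy, nxt))
    }
  }
  rec(matrix(0L, 1, 2))
  best
}

# random self-avoiding walk by greedy growth with restart on dead ends
randomSAWConformation <- function(n) {
  syms <- names(.naiveSteps)
  repeat {
    xy <- matrix(0L, 1, 2)
    symsUsed <- character(0)
    ok <- TRUE
    for (i in seq_len(n - 1L)) {
      cand <- sample(syms)
      placed <- FALSE
      for (s in cand) {
        nxt <- xy[nrow(xy), ] + .naiveSteps[[s]]
        if (!any(xy[, 1] == nxt[1] & xy[, 2] == nxt[2])) {
          xy <- rbind(xy, nxt)
          symsUsed <- c(symsUsed, s)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(Conformation(symsUsed))
  }
}

randomHPString <- function(n) {
  paste(sample(c("H", "P"), n, replace = TRUE), collapse = "")
}

randomFoldConformation <- function(m) {
  Conformation(sample(names(.naiveSteps), m, replace = TRUE))
}
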