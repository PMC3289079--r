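#' Construct an HP sequence
#'
#' \code{HPSequence} takes a plain residue string over \code{{H, P}};
#' \code{parseHP} additionally accepts the compact power notation used for
#' the standard benchmarks, e.g. \code{"(HP)^2PH(HP)^2(PH)^2HP(PH)^2"} or
#' \code{"H^2P^2(HP^2)^6H^2"}, with arbitrarily nested parentheses.
#' Expansion is purely syntactic: concatenation left to right, \code{^k}
#' meaning k-fold repetition.
#'
#' @param x Character string: residues, or power notation for
#'   \code{parseHP}.
#' @return An \linkS4class{HPSequence}.
#' @examples
#' parseHP("H^2P^2(HP^2)^6H^2")   # 24 residues
#' parseHP("((PH)^2)^3")          # "PHPHPHPHPHPH"
#' HPSequence("HPHP")
#' @aliases parseHP
#' @export
HPSequence <- function(x) {
  new("HPSequence", residues = as.character(x))
}

#' @rdname HPSequence
#' @export
parseHP <- function(x) {
  HPSequence(expandHPNotation(x))
}

#' Expand HP power notation to a plain residue string
#'
#' @param text Notation string over \code{H}, \code{P}, parentheses and
#'   \code{^k} exponents (k >= 1). Whitespace is ignored.
#' @return Plain character string of residues.
#' @examples
#' expandHPNotation("(HP)^3")
#' @export
expandHPNotation <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("'text' must be a single string")
  }
  text <- gsub("[[:space:]]", "", text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  err <- function(msg, at) {
    stop(sprintf("HP notation error at position %d: %s", at, msg),
         call. = FALSE)
  }
  parseNumber <- function() {
    start <- i
    while (i <= n && chars[i] %in% as.character(0:9)) i <<- i + 1L
    if (i == start) err("expected an exponent after '^'", start)
    k <- suppressWarnings(as.integer(paste(chars[start:(i - 1L)],
                                           collapse = "")))
    if (is.na(k) || k <= 0L) err("exponent must be a positive integer", start)
    k
  }
  parseExpr <- function(openAt) {
    out <- ""
    repeat {
      if (i > n) {
        if (!is.na(openAt)) err("unbalanced '(': missing ')'", openAt)
        return(out)
      }
      ch <- chars[i]
      if (ch == ")") {
        if (is.na(openAt)) err("unmatched ')'", i)
        return(out)
      }
      piece <- NULL
      if (ch %in% c("H", "P")) {
        piece <- ch
        i <<- i + 1L
      } else if (ch == "(") {
        open <- i
        i <<- i + 1L
        piece <- parseExpr(open)
        i <<- i + 1L # consume ')'
      } else {
        err(sprintf("unexpected character '%s'", ch), i)
      }
      if (i <= n && chars[i] == "^") {
        i <<- i + 1L
        piece <- strrep(piece, parseNumber())
      }
      out <- paste0(out, piece)
    }
  }
  res <- parseExpr(NA_integer_)
  if (nchar(res) == 0L) err("empty sequence", 1L)
  res
}

#' @rdname HPSequence
#' @param object,x An \linkS4class{HPSequence}.
#' @export
setMethod("hpResidues", "HPSequence", function(x) x@residues)

#' @rdname HPSequence
#' @export
setMethod("nResidues", "HPSequence", function(x) nchar(x@residues))

#' @rdname HPSequence
#' @export
setMethod("length", "HPSequence", function(x) nchar(x@residues))

#' @rdname HPSequence
#' @export
setMethod("as.character", "HPSequence", function(x) x@residues)

setMethod("show", "HPSequence", function(object) {
  n <- nResidues(object)
  r <- hpResidues(object)
  cat(sprintf("HPSequence of %d residues (%d H, %d P)\n", n,
              sum(.residueIsH(object)), n - sum(.residueIsH(object))))
  if (n <= 70) cat(" ", r, "\n") else
    cat(" ", substr(r, 1, 67), "...\n")
})

.residueChars <- function(seq) {
  strsplit(hpResidues(seq), "", fixed = TRUE)[[1]]
}

.residueIsH <- function(seq) {
  .residueChars(seq) == "H"
}

#' Construct a conformation from fold symbols
#'
#' \code{Conformation} takes a character vector of direction symbols;
#' \code{parseFoldString} parses the dash-separated text form
#' (e.g. \code{"R-RU-LU"}) used in conformation files.
#'
#' @param x Character vector of symbols, or a dash-separated string for
#'   \code{parseFoldString}.
#' @return A \linkS4class{Conformation}.
#' @examples
#' Conformation(c("R", "RU", "LU"))
#' parseFoldString("R-RU-LU")
#' @aliases parseFoldString folds foldString
#' @export
Conformation <- function(x = character()) {
  new("Conformation", folds = as.character(x))
}

#' @rdname Conformation
#' @export
parseFoldString <- function(x) {
  if (!is.character(x) || length(x) != 1L) stop("'x' must be a single string")
  if (nchar(x) == 0L) return(Conformation())
  Conformation(strsplit(x, "-", fixed = TRUE)[[1]])
}

#' @rdname Conformation
#' @param object An object.
#' @export
setMethod("folds", "Conformation", function(x) x@folds)

#' @rdname Conformation
#' @export
setMethod("foldString", "Conformation", function(x) {
  paste(x@folds, collapse = "-")
})

#' @rdname Conformation
#' @export
setMethod("length", "Conformation", function(x) length(x@folds))

setMethod("show", "Conformation", function(object) {
  cat(sprintf("Conformation with %d folds\n", length(object@folds)))
  if (length(object@folds)) cat(" ", foldString(object), "\n")
})

#' Decode a conformation to lattice coordinates
#'
#' Places the first residue at the origin and follows the fold string; the
#' walk is translation-normalised but not checked for self-avoidance
#' (collisions are detected separately by \code{\link{isSelfAvoiding}}).
#'
#' @param conf A \linkS4class{Conformation}.
#' @return Integer matrix with columns \code{x}, \code{y} and one row per
#'   residue.
#' @examples
#' decodeConformation(Conformation(c("R", "RU")))
#' @export
decodeConformation <- function(conf) {
  stopifnot(is(conf, "Conformation"))
  m <- .cpp_decode(.dirIndex(conf@folds))
  colnames(m) <- c("x", "y")
  m
}

#' Test a decoded walk for self-avoidance
#'
#' @param walk Coordinate matrix from \code{\link{decodeConformation}}, or a
#'   \linkS4class{Conformation} (decoded first).
#' @return \code{TRUE} iff all residue coordinates are pairwise distinct.
#' @examples
#' isSelfAvoiding(Conformation(c("R", "RU")))
#' isSelfAvoiding(Conformation(c("R", "L"))) # immediate backtrack
#' @export
isSelfAvoiding <- function(walk) {
  if (is(walk, "Conformation")) walk <- decodeConformation(walk)
  anyDuplicated(walk) == 0L
}

#' Count H-H topological contacts of a walk
#'
#' A topological contact is a pair of hydrophobic residues that are
#' non-adjacent in the sequence (separation > 1) but occupy neighbouring
#' lattice sites. Contacts are counted on the coordinates as given, whether
#' or not the walk is self-avoiding.
#'
#' @param seq An \linkS4class{HPSequence}.
#' @param walk Coordinate matrix of the same length, or a
#'   \linkS4class{Conformation}.
#' @return Non-negative integer count.
#' @examples
#' countHHContacts(HPSequence("HHH"), Conformation(c("R", "LU")))
#' @export
countHHContacts <- function(seq, walk) {
  stopifnot(is(seq, "HPSequence"))
  if (is(walk, "Conformation")) walk <- decodeConformation(walk)
  if (nrow(walk) != nResidues(seq)) {
    stop("walk length does not match the number of residues")
  }
  H <- which(.residueIsH(seq))
  if (length(H) < 2L) return(0L)
  pairs <- utils::combn(H, 2L)
  keep <- pairs[2L, ] - pairs[1L, ] > 1L
  if (!any(keep)) return(0L)
  a <- walk[pairs[1L, keep], , drop = FALSE]
  b <- walk[pairs[2L, keep], , drop = FALSE]
  sum(areNeighbors(a, b))
}

#' Free energy of a self-avoiding conformation
#'
#' Standard HP contact energy: each H-H topological contact contributes -1;
#' everything else contributes 0. Folding seeks the conformation of minimum
#' free energy.
#'
#' @param seq An \linkS4class{HPSequence}.
#' @param conf A self-avoiding \linkS4class{Conformation} with
#'   \code{length(conf) == nResidues(seq) - 1}.
#' @return Integer energy (<= 0).
#' @seealso \code{\link{hpFitness}} for the penalised score that tolerates
#'   collisions.
#' @examples
#' hpEnergy(HPSequence("HHH"), Conformation(c("R", "LU"))) # -1
#' @export
hpEnergy <- function(seq, conf) {
  stopifnot(is(seq, "HPSequence"), is(conf, "Conformation"))
  if (length(conf) != nResidues(seq) - 1L) {
    stop("conformation must have exactly n - 1 folds")
  }
  walk <- decodeConformation(conf)
  if (!isSelfAvoiding(walk)) {
    stop("infeasible conformation: the decoded walk is not self-avoiding")
  }
  -countHHContacts(seq, walk)
}

#' Penalised fitness of an arbitrary conformation
#'
#' For a self-avoiding conformation this equals \code{\link{hpEnergy}}. A
#' colliding conformation scores \code{-contacts + penalty * collidingPairs},
#' where colliding pairs are residue pairs occupying the same site. With the
#' default penalty of \code{4 * n} any collision scores strictly worse than
#' every valid conformation (a residue can take part in at most four H-H
#' contacts), so optima returned by the search are always feasible while the
#' search space itself stays unrestricted.
#'
#' @param seq An \linkS4class{HPSequence}.
#' @param conf A \linkS4class{Conformation} with n - 1 folds.
#' @param penaltyPerCollision Positive number; default \code{4 * nResidues(seq)}.
#' @return Numeric fitness; lower is better.
#' @examples
#' hpFitness(HPSequence("HHH"), Conformation(c("R", "L"))) # one collision
#' @export
hpFitness <- function(seq, conf, penaltyPerCollision = NULL) {
  stopifnot(is(seq, "HPSequence"), is(conf, "Conformation"))
  if (length(conf) != nResidues(seq) - 1L) {
    stop("conformation must have exactly n - 1 folds")
  }
  penalty <- .resolvePenalty(penaltyPerCollision, nResidues(seq))
  walk <- decodeConformation(conf)
  key <- paste(walk[, 1], walk[, 2])
  tab <- table(key)
  collisions <- sum(tab * (tab - 1) / 2)
  -countHHContacts(seq, walk) + penalty * collisions
}

.resolvePenalty <- function(penalty, n) {
  if (is.null(penalty) || is.na(penalty)) 4 * n else penalty
}

#' Rigidly rotate a conformation
#'
#' Applies a 60-degree multiple rotation to every fold; the decoded walk is
#' the rigid rotation of the original about the origin, so self-avoidance
#' and energy are preserved.
#'
#' @param conf A \linkS4class{Conformation}.
#' @param steps Integer in 1..5 (units of 60 degrees, counter-clockwise).
#' @return The rotated \linkS4class{Conformation}.
#' @export
rotateConformation <- function(conf, steps) {
  stopifnot(is(conf, "Conformation"))
  Conformation(rotateDirection(conf@folds, steps))
}

#' Reverse a conformation
#'
#' Reverses the fold string and replaces every direction by its opposite:
#' the walk traversed from the last residue to the first. Energy of the
#' reversed sequence on the reversed conformation equals the original.
#'
#' @param conf A \linkS4class{Conformation}.
#' @return The reversed \linkS4class{Conformation}.
#' @export
reverseConformation <- function(conf) {
  stopifnot(is(conf, "Conformation"))
  if (length(conf) == 0L) return(conf)
  Conformation(rev(oppositeDirection(conf@folds)))
}
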