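#' Read and write HP sequences in FASTA-like files
#'
#' Header lines start with \code{>name}; sequence lines may be plain
#' \code{H}/\code{P} strings or power notation (auto-detected by the
#' presence of digits, carets or parentheses) and may span several lines,
#' which are concatenated before expansion.
#'
#' @param path File path.
#' @return \code{readHPFasta}: a named list of \linkS4class{HPSequence}s.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">toy", "(HP)^3"), tf)
#' readHPFasta(tf)
#' @export
readHPFasta <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nchar(lines) > 0]
  if (length(lines) == 0) stop("empty file: ", path)
  isHeader <- startsWith(lines, ">")
  if (!isHeader[1]) stop("file must start with a '>' header line")
  group <- cumsum(isHeader)
  out <- list()
  for (g in unique(group)) {
    chunk <- lines[group == g]
    name <- sub("^>\\s*", "", chunk[1])
    body <- paste(chunk[-1], collapse = "")
    if (nchar(body) == 0) stop("record '", name, "' has no sequence")
    out[[name]] <- if (grepl("[0-9^()]", body)) {
      parseHP(body)
    } else {
      HPSequence(body)
    }
  }
  out
}

#' @rdname readHPFasta
#' @param seqs Named list of \linkS4class{HPSequence}s (or a single one).
#' @return \code{writeHPFasta}: \code{path}, invisibly.
#' @export
writeHPFasta <- function(seqs, path) {
  if (is(seqs, "HPSequence")) seqs <- list(seq1 = seqs)
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  lines <- unlist(lapply(names(seqs), function(nm) {
    c(paste0(">", nm), hpResidues(seqs[[nm]]))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write conformation records
#'
#' One tab-separated record per line: name, dash-separated fold string, and
#' energy, e.g. \code{seq1<TAB>R-RU-LU<TAB>-2}.
#'
#' @param path File path.
#' @return \code{readConformations}: a data frame with columns \code{name},
#'   \code{foldString}, \code{energy}, plus a \code{conformations} attribute
#'   holding the parsed \linkS4class{Conformation}s as a named list.
#' @export
readConformations <- function(path) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("name", "foldString", "energy"),
                   stringsAsFactors = FALSE)
  confs <- lapply(df$foldString, parseFoldString)
  names(confs) <- df$name
  attr(df, "conformations") <- confs
  df
}

#' @rdname readConformations
#' @param confs Named list of \linkS4class{Conformation}s.
#' @param energies Numeric vector of energies, one per conformation.
#' @return \code{writeConformations}: \code{path}, invisibly.
#' @export
writeConformations <- function(confs, energies, path) {
  if (is(confs, "Conformation")) confs <- list(seq1 = confs)
  if (length(confs) != length(energies)) {
    stop("one energy per conformation required")
  }
  if (is.null(names(confs)) || any(names(confs) == "")) {
    names(confs) <- paste0("seq", seq_along(confs))
  }
  lines <- vapply(seq_along(confs), function(i) {
    paste(names(confs)[i], foldString(confs[[i]]), energies[i], sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GA configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of \code{\link{gaConfig}}; missing keys keep
#' their defaults and unknown keys are an error. YAML files need the
#' \pkg{yaml} package, JSON files \pkg{jsonlite}.
#'
#' @param path File path ending in \code{.yaml}/\code{.yml} or \code{.json}.
#' @return A \linkS4class{GAConfig}.
#' @export
readGAConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("reading JSON configs requires the 'jsonlite' package")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml, .yml or .json")
  }
  known <- names(formals(gaConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(gaConfig, vals)
}
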