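#' Read a character matrix from a simplified NEXUS file
#'
#' Accepts a NEXUS file containing exactly one `DATA` (or `CHARACTERS`)
#' block with `DIMENSIONS NTAX=... NCHAR=...` and a `MATRIX` section whose
#' state symbols are single characters. `?` denotes missing data; by
#' default `-` (gap) is also treated as missing. A missing cell expands to
#' the full observed alphabet of its character (the set of non-missing
#' symbols seen in that column), which is the neutral choice for parsimony
#' optimization.
#'
#' @param path Path to the NEXUS file.
#' @param gap_as_state Treat `-` as a regular fifth state instead of
#'   missing data.
#' @return A `character_matrix` object: a list with elements `taxa`
#'   (ordered labels), `n_char`, `raw` (taxa x characters symbol matrix),
#'   `alphabet` (per-character observed symbols, sorted) and `cells`
#'   (per-character list of per-taxon allowed-state sets).
#' @export
read_nexus_matrix <- function(path, gap_as_state = FALSE) {
  if (!file.exists(path))
    stop("matrix file not found: ", path, call. = FALSE)
  parse_nexus_data(paste(readLines(path, warn = FALSE), collapse = "\n"),
                   gap_as_state = gap_as_state)
}

#' @rdname read_nexus_matrix
#' @param text NEXUS file content as a single character scalar.
#' @export
parse_nexus_data <- function(text, gap_as_state = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  n_blocks <- length(gregexpr("begin\\s+(data|characters)\\s*;",
                              tolower(text))[[1L]])
  if (!grepl("begin\\s+(data|characters)\\s*;", tolower(text)))
    stop("no DATA block found", call. = FALSE)
  if (n_blocks > 1L)
    stop("multiple DATA blocks found (", n_blocks,
         "); exactly one is required", call. = FALSE)
  ntax <- nexus_dimension(text, "ntax")
  nchar_decl <- nexus_dimension(text, "nchar")

  # CHARACTERS blocks carry the same payload; normalize for the reader
  norm <- gsub("begin\\s+characters\\s*;", "BEGIN DATA;", text,
               ignore.case = TRUE)
  tmp <- tempfile(fileext = ".nex")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(norm, tmp)
  raw_list <- tryCatch(ape::read.nexus.data(tmp), error = function(e)
    stop("could not parse NEXUS matrix: ", conditionMessage(e),
         call. = FALSE))

  taxa <- names(raw_list)
  if (length(taxa) != ntax)
    stop("declared NTAX=", ntax, " but ", length(taxa),
         " taxon rows parsed", call. = FALSE)
  lens <- vapply(raw_list, length, integer(1))
  if (any(lens != nchar_decl))
    stop("declared NCHAR=", nchar_decl, " but row length(s) ",
         paste(unique(lens[lens != nchar_decl]), collapse = ", "),
         " parsed (taxa: ",
         paste(taxa[lens != nchar_decl], collapse = ", "), ")",
         call. = FALSE)
  raw <- do.call(rbind, lapply(raw_list, toupper))
  rownames(raw) <- taxa
  new_character_matrix(raw, gap_as_state = gap_as_state)
}

nexus_dimension <- function(text, key) {
  m <- regmatches(tolower(text),
                  regexpr(paste0(key, "\\s*=\\s*[0-9]+"), tolower(text)))
  if (length(m) == 0L)
    stop("DIMENSIONS ", toupper(key), " not found", call. = FALSE)
  as.integer(sub(paste0(key, "\\s*=\\s*"), "", m))
}

#' Build a character matrix from a symbol matrix
#'
#' @param raw Character matrix (taxa in rows, characters in columns) of
#'   single-character state symbols, with `?` for missing data.
#' @param gap_as_state Treat `-` as a regular state instead of missing.
#' @return A `character_matrix` object.
#' @export
new_character_matrix <- function(raw, gap_as_state = FALSE) {
  stopifnot(is.matrix(raw), is.character(raw), !is.null(rownames(raw)))
  missing_syms <- if (gap_as_state) "?" else c("?", "-")
  n_char <- ncol(raw)
  alphabet <- vector("list", n_char)
  cells <- vector("list", n_char)
  for (j in seq_len(n_char)) {
    col <- raw[, j]
    obs <- sort(unique(col[!(col %in% missing_syms)]))
    alphabet[[j]] <- obs
    cells[[j]] <- lapply(col, function(s) {
      if (s %in% missing_syms) obs else s
    })
    names(cells[[j]]) <- rownames(raw)
  }
  structure(list(taxa = rownames(raw), n_char = n_char, raw = raw,
                 alphabet = alphabet, cells = cells,
                 gap_as_state = gap_as_state),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("Character matrix: ", length(x$taxa), " taxa x ", x$n_char,
      " characters\n", sep = "")
  cat("Taxa:", paste(utils::head(x$taxa, 8), collapse = ", "),
      if (length(x$taxa) > 8) "..." else "", "\n")
  invisible(x)
}

#' Write a character matrix as a simplified NEXUS DATA block
#'
#' @param m A `character_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nexus_matrix <- function(m, path) {
  stopifnot(inherits(m, "character_matrix"))
  symbols <- sort(unique(unlist(m$alphabet)))
  rows <- paste0(format(m$taxa, width = max(nchar(m$taxa)) + 2L),
                 apply(m$raw, 1L, paste, collapse = ""))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               paste0("DIMENSIONS NTAX=", length(m$taxa),
                      " NCHAR=", m$n_char, ";"),
               paste0("FORMAT SYMBOLS=\"",
                      paste(symbols, collapse = ""),
                      "\" MISSING=? GAP=-;"),
               "MATRIX", rows, ";", "END;"), path)
  invisible(path)
}
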