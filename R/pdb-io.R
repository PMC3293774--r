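#' @useDynLib furdock, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate arrange group_by ungroup summarise bind_rows
#'   left_join select distinct slice_max row_number n
#' @importFrom rlang .data
NULL

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

DNA_RESNAMES <- c("DA", "DC", "DG", "DT", "A", "C", "G", "T",
                  "ADE", "CYT", "GUA", "THY")

#' Atom-table structures
#'
#' A structure is represented as a tibble with one row per atom and columns
#' `record` (ATOM/HETATM), `atom` (atom name), `element`, `chain`, `resid`
#' (residue name), `resno` (author numbering), `insert`, `x`, `y`, `z`
#' (Angstrom), `occ`, `b` and `het` (logical heteroatom flag).  All
#' user-facing functions take and return this shape so analyses chain with
#' the pipe.
#'
#' @param df a data frame with at least `atom`, `chain`, `resid`, `resno`,
#'   `x`, `y`, `z`.
#' @return A structure tibble with the full column set, in input order.
#' @export
as_structure <- function(df) {
  df <- as_tibble(df)
  need <- c("atom", "chain", "resid", "resno", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("as_structure: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(df)) stop("as_structure: empty structure", call. = FALSE)
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    stop("as_structure: non-finite coordinates", call. = FALSE)
  }
  if (!"record" %in% names(df)) df$record <- "ATOM"
  if (!"element" %in% names(df)) df$element <- guess_element(df$atom, df$record)
  if (!"insert" %in% names(df)) df$insert <- ""
  if (!"occ" %in% names(df)) df$occ <- 1
  if (!"b" %in% names(df)) df$b <- 0
  if (!"het" %in% names(df)) df$het <- df$record == "HETATM"
  df[, c("record", "atom", "element", "chain", "resid", "resno", "insert",
         "x", "y", "z", "occ", "b", "het")]
}

guess_element <- function(atom, record = "ATOM") {
  metals <- c("ZN", "FE", "MN", "MG", "NA", "CL", "CA", "NI", "CU", "CO", "K")
  vapply(seq_along(atom), function(i) {
    nm <- toupper(gsub("[^A-Za-z]", "", atom[i]))
    if (!nzchar(nm)) return("X")
    if (record[i] == "HETATM" && nm %in% metals) return(nm)
    substr(nm, 1, 1)
  }, character(1))
}

parse_num <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  bad <- is.na(v) & !grepl("^\\s*$", s)
  bad <- bad | is.na(v) & what == "coordinate"
  if (any(is.na(v)) && what == "coordinate") {
    stop(sprintf("PDB parse error at line %d: malformed %s field '%s'",
                 lineno[which(is.na(v))[1]], what,
                 trimws(s[which(is.na(v))[1]])), call. = FALSE)
  }
  v
}

#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM records (fixed-width PDB format) into a structure
#' tibble.  Metal and water heteroatoms are retained and flagged `het`.
#' Only the first model of a multi-model file is read, and only the
#' highest-occupancy conformer of alternate-location groups is kept.
#'
#' @param source a file path, or PDB-format text (single string with
#'   newlines or a character vector of lines).
#' @return A structure tibble (see [as_structure()]).
#' @examples
#' pdb <- write_structure(build_bdna("ACGT"))
#' s <- read_structure(pdb)
#' @export
read_structure <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE))
  }
  if (!length(lines) || all(!nzchar(trimws(lines)))) {
    stop("read_structure: empty input", call. = FALSE)
  }
  # first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1)]
  rec <- substr(lines, 1, 6)
  keep <- grepl("^(ATOM|HETATM)", rec)
  if (!any(keep)) stop("read_structure: no ATOM/HETATM records", call. = FALSE)
  ln <- which(keep)
  lines <- lines[keep]
  field <- function(a, b) substr(lines, a, b)
  x <- parse_num(field(31, 38), ln, "coordinate")
  y <- parse_num(field(39, 46), ln, "coordinate")
  z <- parse_num(field(47, 54), ln, "coordinate")
  occ <- suppressWarnings(as.numeric(field(55, 60)))
  occ[is.na(occ)] <- 1
  b <- suppressWarnings(as.numeric(field(61, 66)))
  b[is.na(b)] <- 0
  record <- trimws(field(1, 6))
  s <- tibble(
    record = record,
    atom = trimws(field(13, 16)),
    alt = trimws(field(17, 17)),
    resid = trimws(field(18, 20)),
    chain = trimws(field(22, 22)),
    resno = suppressWarnings(as.integer(trimws(field(23, 26)))),
    insert = trimws(field(27, 27)),
    x = x, y = y, z = z, occ = occ, b = b,
    element = trimws(field(77, 78)),
    line = ln
  )
  if (any(is.na(s$resno))) {
    stop(sprintf("PDB parse error at line %d: malformed residue number",
                 s$line[which(is.na(s$resno))[1]]), call. = FALSE)
  }
  noelem <- !nzchar(s$element)
  s$element[noelem] <- guess_element(s$atom[noelem], s$record[noelem])
  # altloc policy: keep the highest-occupancy conformer per atom site
  s <- s |>
    group_by(.data$chain, .data$resno, .data$insert, .data$atom) |>
    slice_max(.data$occ, n = 1, with_ties = TRUE) |>
    filter(.data$alt == sort(.data$alt)[1]) |>
    ungroup() |>
    arrange(.data$line)
  s$het <- s$record == "HETATM"
  s <- s[, c("record", "atom", "element", "chain", "resid", "resno",
             "insert", "x", "y", "z", "occ", "b", "het")]
  as_structure(s)
}

#' Write a structure as PDB-format text
#'
#' Emits ATOM/HETATM records with a TER record closing each chain and a
#' final END.  Output is byte-deterministic for identical input.
#'
#' @param s a structure tibble.
#' @param path optional file path; when given the text is also written there.
#' @return The PDB text, invisibly when `path` is given.
#' @export
write_structure <- function(s, path = NULL) {
  s <- as_structure(s)
  if (any(nchar(s$atom) > 4)) {
    stop("write_structure: atom name longer than 4 characters", call. = FALSE)
  }
  if (any(nchar(s$chain) > 1)) {
    stop("write_structure: chain id longer than 1 character", call. = FALSE)
  }
  fmt_atom <- function(a, el) {
    # single-letter elements start in column 14 unless the name fills 4 cols
    ifelse(nchar(a) == 4 | nchar(el) == 2,
           sprintf("%-4s", a), sprintf(" %-3s", a))
  }
  out <- character(0)
  serial <- 0L
  chains <- unique(s$chain)
  for (ch in chains) {
    sub <- s[s$chain == ch, ]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      out <- c(out, sprintf(
        "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        sub$record[i], serial %% 100000L, fmt_atom(sub$atom[i], sub$element[i]),
        "", sub$resid[i], ch, sub$resno[i] %% 10000L, sub$insert[i],
        sub$x[i], sub$y[i], sub$z[i], sub$occ[i], sub$b[i],
        toupper(sub$element[i])))
    }
    last <- sub[nrow(sub), ]
    if (!all(sub$het)) {
      serial <- serial + 1L
      out <- c(out, sprintf("TER   %5d      %-3s %1s%4d",
                            serial %% 100000L, last$resid, ch,
                            last$resno %% 10000L))
    }
  }
  out <- c(out, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(txt))
  }
  txt
}

#' Chain classification and sequence extraction
#'
#' @param s a structure tibble.
#' @param chain chain identifier.
#' @return `chain_kind()` returns `"protein"`, `"dna"` or `"other"`;
#'   `structure_sequence()` returns the one-letter sequence of the chain in
#'   residue-number order.
#' @export
chain_kind <- function(s, chain) {
  res <- unique(s$resid[s$chain == chain & !s$het])
  if (!length(res)) return("other")
  if (mean(res %in% DNA_RESNAMES) > 0.5) return("dna")
  if (mean(res %in% names(AA3TO1)) > 0.5) return("protein")
  "other"
}

#' @rdname chain_kind
#' @export
structure_sequence <- function(s, chain) {
  sub <- s[s$chain == chain & !s$het, ]
  if (!nrow(sub)) stop("structure_sequence: no such chain: ", chain, call. = FALSE)
  sub <- sub[!duplicated(paste(sub$resno, sub$insert)), ]
  sub <- sub[order(sub$resno), ]
  one <- function(r) {
    if (r %in% names(AA3TO1)) return(AA3TO1[[r]])
    if (r %in% DNA_RESNAMES) return(substr(r, nchar(r), nchar(r)))
    "X"
  }
  paste(vapply(sub$resid, one, character(1)), collapse = "")
}

#' @rdname chain_kind
#' @export
dna_chains <- function(s) {
  ch <- unique(s$chain)
  ch[vapply(ch, function(c) chain_kind(s, c) == "dna", logical(1))]
}

#' @rdname chain_kind
#' @export
protein_chains <- function(s) {
  ch <- unique(s$chain)
  ch[vapply(ch, function(c) chain_kind(s, c) == "protein", logical(1))]
}
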