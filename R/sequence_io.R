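#' @keywords internal
"_PACKAGE"

#' Supported m7G regulators
#'
#' The writer complex subunits METTL1 and WDR4 install internal m7G on
#' mRNA; the QKI isoforms 5, 6 and 7 read it. Site tables may name other
#' regulators, which are retained with a warning.
#'
#' @export
REGULATORS <- c("METTL1", "WDR4", "QKI5", "QKI6", "QKI7")

RNA_ALPHABET <- c("A", "C", "G", "U", "N")

#' Create a validated set of RNA sequences
#'
#' Sequences are uppercased, DNA-style `T` is mapped to `U`, and any
#' character outside `A/C/G/U/N` is rejected. The result is a named
#' character vector of class `rna_set`; names are sequence identifiers and
#' must be unique.
#'
#' @param seqs character vector of sequences.
#' @param ids character vector of identifiers (defaults to `names(seqs)`).
#' @return A named character vector of class `rna_set`.
#' @export
rna_set <- function(seqs, ids = names(seqs)) {
  if (length(seqs) == 0L) stop("rna_set: no sequences given")
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("rna_set: every sequence needs a non-empty id")
  }
  if (anyDuplicated(ids)) {
    stop("rna_set: duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- normalize_rna(seqs, ids)
  names(seqs) <- ids
  class(seqs) <- "rna_set"
  seqs
}

# uppercase, T->U, validate alphabet; `who` labels error messages
normalize_rna <- function(seqs, who = seq_along(seqs)) {
  seqs <- chartr("t", "u", toupper(seqs))
  seqs <- chartr("T", "U", seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record ", who[!nzchar(seqs)][1L])
  }
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad)) {
    ch <- gsub("[ACGUN]", "", seqs[bad][1L])
    stop("invalid character(s) '", substr(ch, 1L, 5L),
         "' in record ", who[bad][1L],
         " (allowed: A, C, G, U, N; T is accepted and mapped to U)")
  }
  seqs
}

#' @export
print.rna_set <- function(x, ...) {
  cat("rna_set with", length(x), "sequence(s)\n")
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    s <- unclass(x)[[i]]
    cat(sprintf("  %s (%d nt) %s%s\n", names(x)[i], nchar(s),
                substr(s, 1L, 40L), if (nchar(s) > 40L) "..." else ""))
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' Read RNA sequences from a FASTA file
#'
#' Records are normalized on ingest: uppercased, `T` mapped to `U`, and
#' validated against the `A/C/G/U/N` alphabet. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return An [rna_set].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no FASTA records in ", path)
  seqs <- as.character(set)
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) {
    stop("empty FASTA header at record ", which(!nzchar(ids))[1L])
  }
  rna_set(seqs, ids)
}

#' Write RNA sequences to a FASTA file
#'
#' Standard FASTA with a 60-column line wrap.
#'
#' @param records an [rna_set] (or named character vector of sequences).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (length(records) == 0L) stop("write_fasta: empty record collection")
  if (!inherits(records, "rna_set")) records <- rna_set(records)
  set <- Biostrings::BStringSet(unclass(records))
  names(set) <- names(records)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a table of regulator substrate sites
#'
#' Tab-delimited with header columns `transcript_id`, `position`,
#' `regulator` and optionally `label`. Positions are 1-based and must point
#' at a guanine (checked when windows are extracted, since the table does
#' not carry the sequence). When `label` is absent every row is taken as
#' positive. Duplicate (transcript, position, regulator) rows collapse to
#' one; unknown regulator names are kept with a warning.
#'
#' @param path path to the TSV file.
#' @return A `data.frame` with columns `transcript_id`, `position`
#'   (integer), `regulator`, `label` (`"positive"`/`"negative"`).
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "regulator")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("site table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(tab$position))
  bad <- which(is.na(pos) | pos < 1L | as.character(pos) != trimws(tab$position))
  if (length(bad)) {
    stop("site table ", path, ", line ", bad[1L] + 1L,
         ": position '", tab$position[bad[1L]],
         "' is not a positive integer")
  }
  lab <- if ("label" %in% names(tab)) tolower(trimws(tab$label)) else
    rep("positive", nrow(tab))
  ok <- lab %in% c("positive", "negative")
  if (any(!ok)) {
    stop("site table ", path, ", line ", which(!ok)[1L] + 1L,
         ": label must be 'positive' or 'negative', got '",
         lab[!ok][1L], "'")
  }
  reg <- trimws(tab$regulator)
  unk <- setdiff(unique(reg), REGULATORS)
  if (length(unk)) {
    warning("site table ", path, ": unknown regulator name(s) retained: ",
            paste(unk, collapse = ", "))
  }
  out <- data.frame(transcript_id = trimws(tab$transcript_id),
                    position = pos, regulator = reg, label = lab,
                    stringsAsFactors = FALSE)
  out[!duplicated(out[c("transcript_id", "position", "regulator")]), ,
      drop = FALSE]
}

#' Write a site table
#'
#' @param sites data.frame as returned by [read_site_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# validate a labeled-window data.frame (window, label, transcript_id, position)
check_windows <- function(windows) {
  stopifnot(is.data.frame(windows),
            all(c("window", "label") %in% names(windows)))
  L <- unique(nchar(windows$window))
  if (length(L) > 1L) stop("windows have mixed lengths: ",
                           paste(L, collapse = ", "))
  if (length(L) == 1L && L %% 2L == 0L) stop("window length must be odd")
  invisible(L)
}

#' Write labeled windows as FASTA with annotated headers
#'
#' Headers follow `>transcript:position|regulator|pos` /
#' `...|neg` so a window file round-trips the label and origin.
#'
#' @param windows data.frame with columns `window`, `label`,
#'   `transcript_id`, `position`.
#' @param path output path.
#' @param regulator regulator name recorded in each header.
#' @return `path`, invisibly.
#' @export
write_window_fasta <- function(windows, path, regulator = "NA") {
  check_windows(windows)
  ids <- sprintf("%s:%d|%s|%s", windows$transcript_id, windows$position,
                 regulator, ifelse(windows$label == "positive", "pos", "neg"))
  write_fasta(rna_set(windows$window, ids), path)
}
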