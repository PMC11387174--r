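#' Extract a fixed-length window centred on a guanine site
#'
#' Returns the substring of length `L` centred at `position` (1-based,
#' inclusive). Positions falling outside the transcript are padded with
#' `N`, so near-edge sites are kept rather than discarded.
#'
#' @param transcript a single RNA sequence (character scalar).
#' @param position 1-based position of the site; the base there must be G.
#' @param L odd window length.
#' @param id transcript id used in error messages.
#' @return Character scalar of length-`L` window sequence.
#' @export
extract_window <- function(transcript, position, L, id = "transcript") {
  if (L %% 2L == 0L) stop("window length L must be odd, got ", L)
  transcript <- normalize_rna(transcript, id)
  len <- nchar(transcript)
  if (position < 1L || position > len) {
    stop("site ", id, ":", position, " outside transcript (length ",
         len, ")")
  }
  centre <- substr(transcript, position, position)
  if (centre != "G") {
    stop("site ", id, ":", position,
         " is not a guanine (found '", centre, "')")
  }
  half <- (L - 1L) %/% 2L
  from <- position - half
  to <- position + half
  core <- substr(transcript, max(1L, from), min(len, to))
  pad_l <- max(0L, 1L - from)
  pad_r <- max(0L, to - len)
  paste0(strrep("N", pad_l), core, strrep("N", pad_r))
}

#' Sample negative guanine sites from a transcript
#'
#' Negative candidates are all G positions on the transcript that are not
#' in `positive_positions`. Up to `n` are drawn uniformly without
#' replacement under `seed`; if fewer candidates exist, all are returned
#' with a shortfall warning.
#'
#' @param transcript a single RNA sequence.
#' @param positive_positions integer vector of known positive G positions.
#' @param n number of negatives requested.
#' @param seed integer seed making the draw reproducible.
#' @param id transcript id for the shortfall message.
#' @return Sorted integer vector of sampled positions.
#' @export
sample_negatives <- function(transcript, positive_positions, n, seed,
                             id = "transcript") {
  stopifnot(n >= 0L)
  transcript <- normalize_rna(transcript, id)
  gpos <- which(strsplit(transcript, "")[[1]] == "G")
  cand <- setdiff(gpos, positive_positions)
  if (length(cand) < n) {
    warning("negative shortfall on ", id, ": wanted ", n, ", only ",
            length(cand), " unlabelled G sites available")
  }
  k <- min(n, length(cand))
  if (k == 0L) return(integer(0))
  withr::with_seed(seed, sort(cand[sample.int(length(cand), k)]))
}

#' Greedy redundancy removal on fixed-length windows
#'
#' Incremental clustering in input order: a window is kept iff its
#' ungapped identity (matching positions / L) to every previously kept
#' window is below `identity_threshold`. This mirrors CD-HIT-style
#' de-redundancy for equal-length short windows, where ungapped identity
#' closely tracks alignment-based identity.
#'
#' @param windows data.frame of labeled windows (column `window`) or a
#'   character vector; all the same length.
#' @param identity_threshold identity at or above which a window is
#'   considered redundant, in (0, 1]; default 0.9.
#' @return The kept rows (or elements), input order preserved.
#' @export
dedupe_greedy <- function(windows, identity_threshold = 0.9) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  seqs <- if (is.data.frame(windows)) windows$window else as.character(windows)
  n <- length(seqs)
  if (n == 0L) return(windows)
  L <- unique(nchar(seqs))
  if (length(L) > 1L) stop("dedupe_greedy: mixed window lengths: ",
                           paste(L, collapse = ", "))
  chars <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                  nrow = n, ncol = L, byrow = TRUE)
  kept <- logical(n)
  kept_rows <- matrix(character(0), ncol = L)
  for (i in seq_len(n)) {
    if (nrow(kept_rows) == 0L) {
      ident <- numeric(0)
    } else {
      ident <- rowSums(kept_rows == matrix(chars[i, ], nrow(kept_rows), L,
                                           byrow = TRUE)) / L
    }
    if (all(ident < identity_threshold)) {
      kept[i] <- TRUE
      kept_rows <- rbind(kept_rows, chars[i, , drop = FALSE])
    }
  }
  if (is.data.frame(windows)) windows[kept, , drop = FALSE] else seqs[kept]
}

#' Stratified train/test split
#'
#' Each class contributes `round(train_fraction * n_class)` windows to the
#' training partition (banker's rounding); assignment within a class is
#' random under `seed`.
#'
#' @param windows data.frame of labeled windows (columns `window`,
#'   `label`).
#' @param train_fraction fraction of each class assigned to training,
#'   in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return List with elements `train` and `test` (data.frames).
#' @export
split_train_test <- function(windows, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1 ",
         "(both partitions must be non-empty)")
  }
  check_windows(windows)
  classes <- split(seq_len(nrow(windows)), windows$label)
  small <- names(classes)[lengths(classes) < 2L]
  if (length(small) || length(classes) < 2L) {
    stop("need at least 2 windows in each class; short: ",
         paste(c(small, setdiff(c("positive", "negative"), names(classes))),
               collapse = ", "))
  }
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(classes, function(idx) {
      n_train <- round(train_fraction * length(idx))
      if (n_train < 1L || n_train >= length(idx)) {
        stop("train_fraction ", train_fraction, " leaves an empty ",
             "partition for a class of size ", length(idx))
      }
      idx[sample.int(length(idx), n_train)]
    }), use.names = FALSE)
  })
  list(train = windows[sort(train_idx), , drop = FALSE],
       test = windows[sort(setdiff(seq_len(nrow(windows)), train_idx)), ,
                      drop = FALSE])
}

# md5 of a serialized R object (used for manifests)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}

#' Build a balanced, de-redundant, split dataset for one regulator
#'
#' Composes the full construction pipeline: per transcript, negatives are
#' drawn 1:1 against the positive sites from unlabelled G positions
#' ([sample_negatives()]); windows of length `L` are extracted around all
#' sites ([extract_window()]); redundancy is removed jointly over both
#' classes, positives first ([dedupe_greedy()]); and the result is split
#' stratified 80/20 ([split_train_test()]). All parameters and counts are
#' recorded in the manifest.
#'
#' @param transcripts an [rna_set].
#' @param sites data.frame of positive sites for one regulator (columns
#'   `transcript_id`, `position`, and optionally `regulator`, `label`).
#' @param L odd window length (default 61).
#' @param seed integer seed driving negative sampling and the split.
#' @param identity_threshold redundancy threshold for [dedupe_greedy()].
#' @param train_fraction training fraction for [split_train_test()].
#' @param exclude_sites optional data.frame of additional sites (e.g.
#'   positives of other regulators) whose positions are excluded from the
#'   negative candidate pool.
#' @return A `dataset_split` list with elements `train`, `test`
#'   (data.frames of labeled windows) and `manifest`.
#' @export
build_dataset <- function(transcripts, sites, L = 61L, seed = 1L,
                          identity_threshold = 0.9, train_fraction = 0.8,
                          exclude_sites = NULL) {
  stopifnot(inherits(transcripts, "rna_set"))
  if (nrow(sites) == 0L) stop("no positive sites given")
  if ("label" %in% names(sites) && any(sites$label != "positive")) {
    stop("build_dataset expects positive sites only")
  }
  regulator <- if ("regulator" %in% names(sites)) {
    reg <- unique(sites$regulator)
    if (length(reg) > 1L) stop("sites span multiple regulators: ",
                               paste(reg, collapse = ", "))
    reg
  } else "NA"
  missing_tx <- setdiff(unique(sites$transcript_id), names(transcripts))
  if (length(missing_tx)) {
    stop("site table references unknown transcript(s): ",
         paste(utils::head(missing_tx, 3), collapse = ", "))
  }

  by_tx <- split(sites$position, sites$transcript_id)
  pos_rows <- list(); neg_rows <- list()
  for (tx in names(by_tx)) {
    seq_tx <- unclass(transcripts)[[tx]]
    pos <- sort(unique(by_tx[[tx]]))
    excl <- pos
    if (!is.null(exclude_sites)) {
      excl <- union(excl,
                    exclude_sites$position[exclude_sites$transcript_id == tx])
    }
    neg <- sample_negatives(seq_tx, excl, n = length(pos),
                            seed = seed + match(tx, names(by_tx)), id = tx)
    pos_rows[[tx]] <- data.frame(
      transcript_id = tx, position = pos,
      window = vapply(pos, function(p) extract_window(seq_tx, p, L, tx),
                      character(1)),
      label = "positive", stringsAsFactors = FALSE)
    if (length(neg)) {
      neg_rows[[tx]] <- data.frame(
        transcript_id = tx, position = neg,
        window = vapply(neg, function(p) extract_window(seq_tx, p, L, tx),
                        character(1)),
        label = "negative", stringsAsFactors = FALSE)
    }
  }
  # positives first, then negatives: dedupe preferentially keeps positives
  windows <- rbind(do.call(rbind, unname(pos_rows)),
                   do.call(rbind, unname(neg_rows)))
  rownames(windows) <- NULL
  n_before <- table(factor(windows$label, c("positive", "negative")))
  windows <- dedupe_greedy(windows, identity_threshold)
  n_after <- table(factor(windows$label, c("positive", "negative")))
  split <- split_train_test(windows, train_fraction, seed = seed)

  count2 <- function(df) c(positive = sum(df$label == "positive"),
                           negative = sum(df$label == "negative"))
  manifest <- list(
    regulator = regulator, window_length = as.integer(L),
    seed = as.integer(seed), identity_threshold = identity_threshold,
    train_fraction = train_fraction,
    counts = list(before_dedupe = as.list(as.integer(n_before)),
                  after_dedupe = as.list(as.integer(n_after)),
                  train = as.list(count2(split$train)),
                  test = as.list(count2(split$test))))
  for (nm in c("before_dedupe", "after_dedupe", "train", "test")) {
    names(manifest$counts[[nm]]) <- c("positive", "negative")
  }
  manifest$content_hash <- object_hash(list(split$train$window,
                                            split$train$label,
                                            split$test$window,
                                            split$test$label))
  structure(list(train = split$train, test = split$test,
                 manifest = manifest),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  m <- x$manifest
  cat("dataset_split for", m$regulator, "\n")
  cat(sprintf("  window length %d, seed %d, identity threshold %.2f\n",
              m$window_length, m$seed, m$identity_threshold))
  cat(sprintf("  train: %d positive / %d negative\n",
              m$counts$train$positive, m$counts$train$negative))
  cat(sprintf("  test:  %d positive / %d negative\n",
              m$counts$test$positive, m$counts$test$negative))
  invisible(x)
}
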