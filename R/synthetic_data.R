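#' Specification for a synthetic motif-planted benchmark
#'
#' Describes a set of i.i.d. background transcripts carrying positive
#' guanine sites whose flanks contain a regulator-style recognition motif
#' (e.g. `GxAG` for METTL1-like writers; `x` matches any base drawn from
#' the background composition). A `noise_rate` fraction of positives is
#' generated without the motif, emulating substrate sites whose signal
#' the model cannot see.
#'
#' @param n_transcripts number of transcripts.
#' @param transcript_length length of each transcript (nt).
#' @param n_positive_sites total number of positive sites, distributed
#'   evenly over transcripts.
#' @param motif motif string over `A/C/G/U/x`; where it overlaps the
#'   central G its character there must be `G` or `x`.
#' @param motif_offset signed offset of the motif start relative to the
#'   central G (0 = motif starts at the site).
#' @param background named probabilities over A, C, G, U; must sum to 1.
#' @param noise_rate fraction of positives planted without the motif,
#'   in \[0, 1\].
#' @param regulator regulator name written into the site table.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_transcripts = 50L, transcript_length = 1000L,
                           n_positive_sites = 500L, motif = "GxAG",
                           motif_offset = 0L,
                           background = c(A = 0.25, C = 0.25,
                                          G = 0.25, U = 0.25),
                           noise_rate = 0.1, regulator = "METTL1",
                           seed = 1L) {
  stopifnot(n_transcripts >= 1L, transcript_length >= 10L,
            n_positive_sites >= 1L, nchar(motif) >= 1L,
            noise_rate >= 0, noise_rate <= 1)
  if (grepl("[^ACGUx]", motif)) {
    stop("motif may only contain A, C, G, U and x, got '", motif, "'")
  }
  background <- background[c("A", "C", "G", "U")]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-9) {
    stop("background composition must name A, C, G, U and sum to 1")
  }
  # the planted site itself must stay a guanine
  centre_in_motif <- 1L - motif_offset
  if (centre_in_motif >= 1L && centre_in_motif <= nchar(motif)) {
    ch <- substr(motif, centre_in_motif, centre_in_motif)
    if (!ch %in% c("G", "x")) {
      stop("motif character over the central G must be 'G' or 'x', got '",
           ch, "'")
    }
  }
  structure(list(n_transcripts = as.integer(n_transcripts),
                 transcript_length = as.integer(transcript_length),
                 n_positive_sites = as.integer(n_positive_sites),
                 motif = motif, motif_offset = as.integer(motif_offset),
                 background = background, noise_rate = noise_rate,
                 regulator = regulator, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate synthetic transcripts with planted positive sites
#'
#' Transcripts are i.i.d. draws from the background composition. Positive
#' sites are placed at near-evenly spaced jittered positions, the centre
#' base is forced to G, and — except for a `noise_rate` fraction — the
#' motif is written into the flank at `motif_offset`. The truth table
#' records which positives actually carry the motif.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `transcripts` (an [rna_set]), `sites` (positive-site
#'   data.frame) and `truth` (data.frame with `motif_planted` flag).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mlen <- nchar(spec$motif)
  margin <- mlen + abs(spec$motif_offset) + 5L
  len <- spec$transcript_length
  usable <- len - 2L * margin
  # sites per transcript, spread as evenly as possible
  per_tx <- rep(spec$n_positive_sites %/% spec$n_transcripts,
                spec$n_transcripts)
  extra <- spec$n_positive_sites %% spec$n_transcripts
  if (extra > 0L) per_tx[seq_len(extra)] <- per_tx[seq_len(extra)] + 1L
  min_sep <- 2L * (mlen + abs(spec$motif_offset)) + 8L
  if (usable < 1L || max(per_tx) * min_sep > usable) {
    stop("infeasible site packing: ", max(per_tx), " sites need ~",
         max(per_tx) * min_sep, " nt of usable transcript, have ",
         max(usable, 0L))
  }
  bases <- c("A", "C", "G", "U")
  withr::with_seed(spec$seed, {
    tx_ids <- sprintf("synth_tx%03d", seq_len(spec$n_transcripts))
    seqs <- character(spec$n_transcripts)
    site_list <- list()
    for (t in seq_len(spec$n_transcripts)) {
      chars <- sample(bases, len, replace = TRUE, prob = spec$background)
      k <- per_tx[t]
      positions <- integer(0)
      if (k > 0L) {
        # evenly spaced slots with jitter of at most a quarter slot,
        # guaranteeing pairwise separation >= slot/2 >= min_sep/2
        slot <- usable / k
        jitter <- sample.int(max(1L, floor(slot / 4)), k, replace = TRUE) -
          floor(max(1L, floor(slot / 4)) / 2)
        positions <- as.integer(margin + round((seq_len(k) - 0.5) * slot) +
                                  jitter)
        positions <- pmin(pmax(positions, margin + 1L), len - margin)
        planted <- stats::runif(k) >= spec$noise_rate
        for (s in seq_len(k)) {
          p <- positions[s]
          chars[p] <- "G"
          if (planted[s]) {
            mstart <- p + spec$motif_offset
            for (m in seq_len(mlen)) {
              ch <- substr(spec$motif, m, m)
              chars[mstart + m - 1L] <-
                if (ch == "x") {
                  if (mstart + m - 1L == p) "G" else
                    sample(bases, 1L, prob = spec$background)
                } else ch
            }
            chars[p] <- "G"  # motif may not overwrite the site
          }
        }
        site_list[[t]] <- data.frame(
          transcript_id = tx_ids[t], position = positions,
          regulator = spec$regulator, label = "positive",
          motif_planted = planted, stringsAsFactors = FALSE)
      }
      seqs[t] <- paste(chars, collapse = "")
    }
    sites <- do.call(rbind, site_list)
    rownames(sites) <- NULL
    list(transcripts = rna_set(seqs, tx_ids),
         sites = sites[c("transcript_id", "position", "regulator", "label")],
         truth = sites[c("transcript_id", "position", "motif_planted")])
  })
}

#' Generate a ready-to-train benchmark dataset
#'
#' Composes [generate_synthetic()] with [build_dataset()]: the canonical
#' end-to-end fixture for exercising the whole pipeline without any
#' external data.
#'
#' @param spec a [synthetic_spec()].
#' @param L odd window length (default 61).
#' @param identity_threshold redundancy threshold (default 0.9).
#' @param train_fraction training fraction (default 0.8).
#' @return A `dataset_split`; its manifest records the generator
#'   parameters under `$synthetic`.
#' @export
make_benchmark <- function(spec, L = 61L, identity_threshold = 0.9,
                           train_fraction = 0.8) {
  gen <- generate_synthetic(spec)
  ds <- build_dataset(gen$transcripts, gen$sites, L = L,
                      seed = spec$seed, identity_threshold = identity_threshold,
                      train_fraction = train_fraction)
  ds$manifest$synthetic <- spec[c("n_transcripts", "transcript_length",
                                  "n_positive_sites", "motif",
                                  "motif_offset", "noise_rate", "seed")]
  ds
}
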