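#' Default regional biomarker set
#'
#' The eight regions reported to lose volume already in preataxic SCA3 and used
#' throughout the package: medulla oblongata, pons, midbrain, pallidum,
#' superior cerebellar peduncle, cerebellar white matter, flocculonodular lobe,
#' and cerebellar anterior lobe (hemispheric volumes summed, mm^3).
#'
#' @return Character vector of eight region names.
#' @export
sca3_regions <- function() {
  c("medulla_oblongata", "pons", "midbrain", "pallidum",
    "superior_cerebellar_peduncle", "cerebellar_white_matter",
    "flocculonodular_lobe", "cerebellar_anterior_lobe")
}

#' Define the atrophy event set
#'
#' An atrophy event is a biomarker crossing a severity threshold. With the
#' default eight regions and thresholds z = 1, 2, 3 (i.e. w = -1, -2, -3) the
#' event space has 24 events. Severity is z = -w, so volume loss maps to
#' increasing z.
#'
#' @param biomarkers Character vector of biomarker names.
#' @param thresholds Numeric vector of increasing severity thresholds applied
#'   to every biomarker (default `c(1, 2, 3)`).
#' @return An object of class `ebm_events`: a list with the event table
#'   (`biomarker`, `threshold`, `label`), `biomarkers`, `thresholds`, and the
#'   event count `n_events`.
#' @export
ebm_events <- function(biomarkers = sca3_regions(), thresholds = c(1, 2, 3)) {
  stopifnot(length(biomarkers) >= 1, !anyDuplicated(biomarkers),
            length(thresholds) >= 1, all(diff(thresholds) > 0))
  tab <- data.frame(
    biomarker = rep(biomarkers, each = length(thresholds)),
    threshold = rep(thresholds, times = length(biomarkers)),
    stringsAsFactors = FALSE
  )
  tab$label <- sprintf("%s|z%g", tab$biomarker, tab$threshold)
  structure(list(table = tab, biomarkers = biomarkers,
                 thresholds = thresholds, n_events = nrow(tab)),
            class = "ebm_events")
}

#' @export
print.ebm_events <- function(x, ...) {
  cat(sprintf("Atrophy event set: %d biomarkers x %d thresholds = %d events\n",
              length(x$biomarkers), length(x$thresholds), x$n_events))
  invisible(x)
}

# 0-based biomarker index per event (for the C++ core)
event_bio0 <- function(events) {
  match(events$table$biomarker, events$biomarkers) - 1L
}

#' Check within-biomarker threshold ordering of a sequence
#'
#' A sequence is valid when, for every biomarker, its lower-threshold events
#' precede its higher-threshold events.
#'
#' @param sequence Integer vector of event indices (1..N) in order.
#' @param events An [ebm_events()] object.
#' @return Logical scalar.
#' @export
is_valid_sequence <- function(sequence, events) {
  N <- events$n_events
  if (length(sequence) != N || anyDuplicated(sequence) ||
      any(sequence < 1L | sequence > N)) {
    return(FALSE)
  }
  tab <- events$table
  for (b in events$biomarkers) {
    idx <- which(tab$biomarker[sequence] == b)
    if (is.unsorted(tab$threshold[sequence[idx]], strictly = TRUE)) return(FALSE)
  }
  TRUE
}

#' Draw a uniform random valid event sequence
#'
#' Draws uniformly over constraint-respecting sequences: a random permutation
#' of events is canonicalized by reassigning, within each biomarker, its
#' thresholds in ascending order across the positions that biomarker occupies.
#'
#' @param events An [ebm_events()] object.
#' @return Integer vector of event indices.
#' @export
random_sequence <- function(events) {
  perm <- sample.int(events$n_events)
  canonicalize_sequence(perm, events)
}

# reassign each biomarker's events ascending in threshold over its positions
canonicalize_sequence <- function(sequence, events) {
  tab <- events$table
  out <- sequence
  for (b in events$biomarkers) {
    pos <- which(tab$biomarker[sequence] == b)
    ids <- sequence[pos]
    out[pos] <- ids[order(tab$threshold[ids])]
  }
  out
}

#' Event positions of a sequence
#'
#' @param sequence Integer vector of event indices in order.
#' @param events An [ebm_events()] object.
#' @return Integer vector of length `n_events`: position (1..N) of each event.
#' @export
sequence_positions <- function(sequence, events) {
  pos <- integer(events$n_events)
  pos[sequence] <- seq_along(sequence)
  pos
}

#' Kendall rank correlation between two event sequences
#'
#' Computed on the event position vectors; 1 means identical orderings.
#'
#' @param seq1,seq2 Integer event-index sequences over the same event set.
#' @param events An [ebm_events()] object.
#' @return Kendall's tau.
#' @export
sequence_kendall <- function(seq1, seq2, events) {
  cor(sequence_positions(seq1, events), sequence_positions(seq2, events),
      method = "kendall")
}

#' Event sequence as labels
#'
#' @param sequence Integer event-index sequence.
#' @param events An [ebm_events()] object.
#' @return Character vector of event labels in sequence order.
#' @export
sequence_labels <- function(sequence, events) {
  events$table$label[sequence]
}

# inverse of sequence_labels
sequence_from_labels <- function(labels, events) {
  idx <- match(labels, events$table$label)
  if (anyNA(idx)) stop("unknown event label(s): ",
                       paste(labels[is.na(idx)], collapse = ", "))
  idx
}
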