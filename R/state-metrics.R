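#' Participant-specific median FC matrix per state
#'
#' For each state, the participant's state matrix is the element-wise median
#' over that participant's windows assigned to the state; a state the
#' participant never visits is marked absent (NULL) and excluded downstream.
#'
#' @param wfc a `windowed_fc`.
#' @param labels integer state labels, one per window.
#' @param k number of states.
#' @return object of class `participant_state_fc` with fields `id`,
#'   `matrices` (list of k symmetric matrices or NULL), `edge_medians`
#'   (list of k edge vectors or NULL), `counts` (windows per state).
#' @export
participant_state_fc <- function(wfc, labels, k) {
  if (length(labels) != n_windows(wfc)) {
    stop("labels (", length(labels), ") and windows (", n_windows(wfc),
         ") differ in length")
  }
  counts <- tabulate(labels, k)
  edge_medians <- vector("list", k)
  matrices <- vector("list", k)
  for (s in seq_len(k)) {
    if (counts[s] == 0) next
    member <- wfc$edges[labels == s, , drop = FALSE]
    med <- as.numeric(cpp_colmedians(member))
    edge_medians[[s]] <- med
    m <- devectorize_upper(med, wfc$n_regions)
    dimnames(m) <- list(wfc$region_labels, wfc$region_labels)
    matrices[[s]] <- m
  }
  structure(list(id = wfc$id, matrices = matrices,
                 edge_medians = edge_medians, counts = counts),
            class = "participant_state_fc")
}

#' Dwell time (occupancy) per state
#'
#' Dwell time of a state is the number of windows the participant's label
#' sequence spends in that state (total occupancy, not mean contiguous run
#' length); the counts sum to the number of windows. Set
#' `run_length = TRUE` for the mean-contiguous-run variant.
#'
#' @param labels integer state labels in `1..k`.
#' @param k number of states.
#' @param run_length if TRUE, return the mean length of contiguous runs per
#'   state instead of occupancy (0 for states never visited).
#' @return named numeric vector of length `k`.
#' @export
dwell_times <- function(labels, k, run_length = FALSE) {
  stopifnot(all(labels >= 1), all(labels <= k))
  if (!run_length) {
    out <- tabulate(labels, k)
  } else {
    r <- rle(labels)
    out <- vapply(seq_len(k), function(s) {
      len <- r$lengths[r$values == s]
      if (length(len) == 0) 0 else mean(len)
    }, numeric(1))
  }
  names(out) <- paste0("state", seq_len(k))
  out
}

#' Number of state transitions in a label sequence
#'
#' @param labels integer state labels.
#' @return count of indices where consecutive labels differ.
#' @export
transition_count <- function(labels) {
  if (length(labels) == 0) stop("empty label sequence")
  sum(labels[-1] != labels[-length(labels)])
}

#' Distribution of transition frequencies
#'
#' Entry (a, b), a != b, is the fraction of all label changes that go from
#' state a to state b; the diagonal is 0 and the matrix is all-zero when no
#' transition occurs.
#'
#' @param labels integer state labels in `1..k`.
#' @param k number of states.
#' @return `k x k` matrix of fractions summing to 1 (or 0).
#' @export
transition_frequencies <- function(labels, k) {
  stopifnot(all(labels >= 1), all(labels <= k))
  out <- matrix(0, k, k)
  if (length(labels) < 2) return(out)
  from <- labels[-length(labels)]
  to <- labels[-1]
  chg <- from != to
  if (!any(chg)) return(out)
  for (idx in which(chg)) out[from[idx], to[idx]] <- out[from[idx], to[idx]] + 1
  out / sum(out)
}

#' Temporal properties of one participant's state sequence
#'
#' @param labels integer state labels in `1..k`.
#' @param k number of states.
#' @param id participant id.
#' @return object of class `temporal_properties` with `dwell`, `transitions`,
#'   `frequencies`.
#' @export
temporal_properties <- function(labels, k, id = NULL) {
  structure(list(id = id,
                 dwell = dwell_times(labels, k),
                 transitions = transition_count(labels),
                 frequencies = transition_frequencies(labels, k)),
            class = "temporal_properties")
}

#' Group-level summaries of temporal properties
#'
#' Group mean dwell time averages over all participants (a state that never
#' occurs for a participant contributes 0); the occurring-participants-only
#' variant is returned alongside. The group transition-frequency distribution
#' is the mean of participant frequency matrices over participants with at
#' least one transition.
#'
#' @param props list of `temporal_properties`.
#' @param groups character group per participant (same order).
#' @return list per group: `mean_dwell`, `mean_dwell_occurring`,
#'   `mean_transitions`, `mean_frequencies`, `n`.
#' @export
group_temporal_summary <- function(props, groups) {
  stopifnot(length(props) == length(groups))
  out <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    dwell <- do.call(rbind, lapply(props[idx], `[[`, "dwell"))
    occurring <- apply(dwell, 2, function(col) {
      if (!any(col > 0)) NA_real_ else mean(col[col > 0])
    })
    trans <- vapply(props[idx], `[[`, numeric(1), "transitions")
    freq_list <- lapply(props[idx], `[[`, "frequencies")
    has_trans <- vapply(freq_list, function(f) sum(f) > 0, logical(1))
    mean_freq <- if (any(has_trans)) {
      Reduce(`+`, freq_list[has_trans]) / sum(has_trans)
    } else {
      freq_list[[1]] * 0
    }
    out[[g]] <- list(mean_dwell = colMeans(dwell),
                     mean_dwell_occurring = occurring,
                     mean_transitions = mean(trans),
                     mean_frequencies = mean_freq,
                     n = length(idx))
  }
  out
}
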