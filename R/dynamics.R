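#' Boolean dynamics of a signed network
#'
#' Ground-truth engine for validating the structural measures. Nodes take
#' ON/OFF states; each non-input node updates to the value of its DNF rule;
#' input nodes hold their state (sustained signal); clamped nodes are frozen
#' (OFF = knockout, ON = constitutive activation).
#'
#' Synchronous updating is deterministic: the trajectory is followed until a
#' state repeats, and the attractor (fixed point or cycle) is reported.
#' Random-asynchronous updating performs, per round, a sequential update of
#' all free nodes in random order; replicates are aggregated into per-node ON
#' frequencies at the horizon, reproducible under `seed`.
#'
#' @param net a [signed_network].
#' @param clamp named logical vector of nodes frozen ON/OFF.
#' @param scheme `"synchronous"` or `"asynchronous"`.
#' @param initial named logical start state; default: inputs ON, rest OFF.
#' @param horizon maximum update rounds.
#' @param replicates asynchronous replicates.
#' @param seed RNG seed for asynchronous updating.
#' @return a `boolean_trajectory`: `on_frequency` (named, at the attractor or
#'   horizon), `steady` (named logical, or NULL if no fixed point),
#'   `attractor_period` (synchronous; NA on horizon exhaustion), `scheme`.
#' @examples
#' tr <- simulate_boolean(fixtures()$chain)
#' tr$steady[["O"]]
#' @export
simulate_boolean <- function(net, clamp = NULL,
                             scheme = c("synchronous", "asynchronous"),
                             initial = NULL, horizon = 50L, replicates = 100L,
                             seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(net, "signed_network"))
  ids <- net$nodes$id
  if (!is.null(clamp)) {
    bad <- setdiff(names(clamp), ids)
    if (length(bad)) stop("clamped node(s) not in network: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  state <- stats::setNames(rep(FALSE, length(ids)), ids)
  state[net$inputs] <- TRUE
  if (!is.null(initial)) state[names(initial)] <- initial
  if (!is.null(clamp)) state[names(clamp)] <- clamp
  free <- setdiff(names(net$rules), names(clamp))

  if (scheme == "synchronous") {
    seen <- new.env(parent = emptyenv())
    traj <- list(state)
    assign(paste(as.integer(state), collapse = ""), 1L, envir = seen)
    period <- NA_integer_
    for (t in seq_len(horizon)) {
      nxt <- state
      for (v in free) nxt[[v]] <- eval_rule(net$rules[[v]], state)
      state <- nxt
      key <- paste(as.integer(state), collapse = "")
      prev <- mget(key, envir = seen, ifnotfound = list(NULL))[[1L]]
      if (!is.null(prev)) {
        period <- length(traj) + 1L - prev
        traj[[length(traj) + 1L]] <- state
        break
      }
      assign(key, length(traj) + 1L, envir = seen)
      traj[[length(traj) + 1L]] <- state
    }
    if (is.na(period)) {
      return(structure(list(on_frequency = stats::setNames(as.numeric(state), ids),
                            steady = NULL, attractor_period = NA_integer_,
                            scheme = scheme, timeout = TRUE),
                       class = "boolean_trajectory"))
    }
    cyc <- traj[(length(traj) - period):(length(traj) - 1L)]
    freq <- colMeans(do.call(rbind, lapply(cyc, as.numeric)))
    names(freq) <- ids
    structure(list(on_frequency = freq,
                   steady = if (period == 1L) cyc[[1L]] else NULL,
                   attractor_period = period, scheme = scheme, timeout = FALSE),
              class = "boolean_trajectory")
  } else {
    if (!is.null(seed)) set.seed(seed)
    finals <- matrix(NA, nrow = replicates, ncol = length(ids),
                     dimnames = list(NULL, ids))
    for (r in seq_len(replicates)) {
      s <- state
      for (t in seq_len(horizon)) {
        for (v in sample(free)) s[[v]] <- eval_rule(net$rules[[v]], s)
      }
      finals[r, ] <- s
    }
    freq <- colMeans(finals)
    structure(list(on_frequency = freq,
                   steady = if (all(freq %in% c(0, 1))) stats::setNames(freq == 1, ids)
                            else NULL,
                   attractor_period = NA_integer_, scheme = scheme, timeout = FALSE),
              class = "boolean_trajectory")
  }
}

#' @export
print.boolean_trajectory <- function(x, ...) {
  cat(sprintf("boolean_trajectory (%s): %s\n", x$scheme,
              if (!is.null(x$steady)) "steady state reached"
              else if (!is.na(x$attractor_period)) sprintf("cycle of period %d", x$attractor_period)
              else "horizon exhausted"))
  print(x$on_frequency)
  invisible(x)
}

output_on <- function(net, traj, consensus = 1) {
  stats::setNames(traj$on_frequency[net$outputs] >= consensus, net$outputs)
}

#' Classify dynamically essential components
#'
#' A component is essential for a perturbation kind when clamping it
#' (knockout = OFF, constitutive activation = ON) drives the output to a
#' state different from the unperturbed model's steady output under sustained
#' input ON. For asynchronous updating the output counts as ON when its
#' ON-frequency reaches `consensus` (default 1, i.e. unanimity over
#' replicates).
#'
#' @inheritParams simulate_boolean
#' @param consensus ON-frequency threshold for calling the output ON.
#' @param baseline_output optional named logical of correct output states;
#'   default: the unperturbed model's.
#' @return tibble with columns `node`, `kind` (knockout/constitutive),
#'   `essential` (logical).
#' @examples
#' classify_essential(fixtures()$and_gate)
#' @export
classify_essential <- function(net, scheme = c("synchronous", "asynchronous"),
                               horizon = 50L, replicates = 100L, seed = NULL,
                               consensus = 1, baseline_output = NULL) {
  scheme <- match.arg(scheme)
  base <- simulate_boolean(net, scheme = scheme, horizon = horizon,
                           replicates = replicates, seed = seed)
  if (isTRUE(base$timeout)) {
    stop("baseline simulation did not reach an attractor within the horizon",
         call. = FALSE)
  }
  correct <- baseline_output %||% output_on(net, base, consensus)
  if (!any(correct)) {
    stop("baseline output is OFF; essentiality against an inactive baseline is undefined",
         call. = FALSE)
  }
  candidates <- setdiff(net$nodes$id, net$outputs)
  rows <- list()
  for (v in candidates) {
    for (kind in c("knockout", "constitutive")) {
      clamp <- stats::setNames(kind == "constitutive", v)
      tr <- simulate_boolean(net, clamp = clamp, scheme = scheme,
                             horizon = horizon, replicates = replicates, seed = seed)
      got <- output_on(net, tr, consensus)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        node = v, kind = kind, essential = !identical(unname(got), unname(correct)))
    }
  }
  dplyr::bind_rows(rows)
}

#' ROC comparison of importance measures against dynamic essentiality
#'
#' Sweeps a decision threshold over the distinct scores of each measure
#' (predict essential when score >= threshold) and reports sensitivity (the
#' fraction of essential components recognized) and specificity (the fraction
#' of non-essential components recognized) at each threshold, plus the best
#' operating point per measure (max sensitivity + specificity). Degenerate
#' truth (all essential or none) yields NaN metrics, flagged via the
#' `defined` column.
#'
#' @param report an `esm_report` from [rank_components()].
#' @param truth named logical vector (or tibble from [classify_essential()]
#'   filtered to one kind) of true essentiality over the same perturbations.
#' @return a `roc_result`: tibble `series` (measure, threshold, sensitivity,
#'   specificity, defined) with attribute `best` (one row per measure).
#' @export
roc_validation <- function(report, truth) {
  if (is.data.frame(truth)) {
    truth <- stats::setNames(truth$essential, truth$node)
  }
  common <- intersect(report$perturbed, names(truth))
  if (!length(common)) stop("no overlap between report and truth node sets", call. = FALSE)
  rep2 <- report[match(common, report$perturbed), , drop = FALSE]
  y <- truth[common]
  measures <- c("e_esm", "e_sp", "e_sigflux", "betweenness")
  series <- list()
  for (m in measures) {
    s <- rep2[[m]]
    ok <- !is.na(s)
    thr <- sort(unique(s[ok]))
    for (t in thr) {
      pred <- s[ok] >= t
      tp <- sum(pred & y[ok]); fn <- sum(!pred & y[ok])
      tn <- sum(!pred & !y[ok]); fp <- sum(pred & !y[ok])
      sens <- if (tp + fn > 0) tp / (tp + fn) else NaN
      spec <- if (tn + fp > 0) tn / (tn + fp) else NaN
      series[[length(series) + 1L]] <- tibble::tibble(
        measure = m, threshold = t, sensitivity = sens, specificity = spec,
        defined = is.finite(sens) && is.finite(spec))
    }
  }
  series <- dplyr::bind_rows(series)
  best <- series |>
    dplyr::filter(.data$defined) |>
    dplyr::group_by(.data$measure) |>
    dplyr::slice_max(.data$sensitivity + .data$specificity, n = 1,
                     with_ties = FALSE) |>
    dplyr::ungroup()
  structure(series, best = best, class = c("roc_result", class(series)))
}

#' @rdname roc_validation
#' @param object a `roc_result`.
#' @param ... unused.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity,
                               colour = .data$measure)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}
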