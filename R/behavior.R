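#' Discrimination index
#'
#' `di = (t_novel - t_familiar) / (t_novel + t_familiar)`: the normalized
#' preference for the novel object (or odor), in `[-1, 1]`. Positive values
#' indicate novelty preference; the index is undefined when both exploration
#' times are zero and invariant to rescaling both times by the same factor.
#'
#' @param t_novel_s,t_familiar_s exploration times in seconds, both >= 0,
#'   not both 0.
#' @return An object of class `"DiscriminationResult"`: list with
#'   `t_novel_s`, `t_familiar_s`, `di`.
#' @examples
#' discriminationIndex(60, 40)$di  # 0.2
#' @export
discriminationIndex <- function(t_novel_s, t_familiar_s) {
  if (t_novel_s < 0 || t_familiar_s < 0)
    stop("exploration times must be non-negative")
  if (t_novel_s + t_familiar_s == 0)
    stop("discrimination index undefined: both exploration times are zero")
  structure(list(t_novel_s = t_novel_s, t_familiar_s = t_familiar_s,
                 di = (t_novel_s - t_familiar_s) /
                   (t_novel_s + t_familiar_s)),
            class = "DiscriminationResult")
}

#' @export
print.DiscriminationResult <- function(x, ...) {
  cat(sprintf("DI = %.3f (novel %.1f s, familiar %.1f s)\n", x$di,
              x$t_novel_s, x$t_familiar_s))
  invisible(x)
}

#' Total exploration time per condition
#'
#' Sums epoch durations per condition. A requested condition with no epochs
#' contributes 0 seconds and is flagged (attribute `"empty"`), not an error.
#'
#' @param events an [EventTable-class].
#' @param conditions conditions to total (default: the conditions present).
#' @return Named numeric vector of seconds, with attribute `"empty"` naming
#'   conditions that had no epochs.
#' @export
explorationTimes <- function(events, conditions = NULL) {
  stopifnot(is(events, "EventTable"))
  ev <- events@events
  if (is.null(conditions)) conditions <- unique(ev$condition)
  unknown <- setdiff(conditions, .event_conditions)
  if (length(unknown))
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  out <- vapply(conditions, function(cc)
    sum(ev$end_s[ev$condition == cc] - ev$start_s[ev$condition == cc]),
    numeric(1))
  attr(out, "empty") <- conditions[!conditions %in% ev$condition]
  out
}

#' Habituation curve and dishabituation from repeated odor presentations
#'
#' Expects odor presentation epochs labeled `<odor>_trial<k>`; per-trial
#' sniffing totals are ordered by presentation time. Dishabituation at each
#' odor switch is the first trial of the new odor minus the last trial of
#' the previous odor (renewed sniffing at a switch indexes odor
#' discrimination).
#'
#' @param events an [EventTable-class] of odor presentations.
#' @return An object of class `"HabituationCurve"`: list with `curve`
#'   (data.frame `odor`, `trial`, `sniff_s`, in presentation order) and
#'   `dishabituation` (named vector, one value per odor switch).
#' @export
habituationCurve <- function(events) {
  stopifnot(is(events, "EventTable"))
  ev <- events@events
  ev <- ev[grepl("_trial\\d+$", ev$label), , drop = FALSE]
  if (!nrow(ev)) stop("no odor presentation epochs (labels '<odor>_trial<k>')")
  sniff <- tapply(ev$end_s - ev$start_s, ev$label, sum)
  first <- tapply(ev$start_s, ev$label, min)
  labs <- names(sort(first))
  agg <- data.frame(odor = sub("_trial\\d+$", "", labs),
                    trial = as.integer(sub("^.*_trial", "", labs)),
                    sniff_s = as.numeric(sniff[labs]),
                    stringsAsFactors = FALSE)
  cnt <- table(agg$odor)
  if (any(cnt < 2))
    stop("fewer than 2 presentations of odor(s): ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  switches <- which(agg$odor[-1L] != agg$odor[-nrow(agg)])
  dis <- agg$sniff_s[switches + 1L] - agg$sniff_s[switches]
  names(dis) <- paste(agg$odor[switches], agg$odor[switches + 1L],
                      sep = "->")
  structure(list(curve = agg, dishabituation = dis),
            class = "HabituationCurve")
}

#' @export
print.HabituationCurve <- function(x, ...) {
  cat(sprintf("Habituation curve: %d presentations of %d odor(s)\n",
              nrow(x$curve), length(unique(x$curve$odor))))
  if (length(x$dishabituation))
    cat("  dishabituation:",
        paste(sprintf("%s %+0.1f s", names(x$dishabituation),
                      x$dishabituation), collapse = ", "), "\n")
  invisible(x)
}
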