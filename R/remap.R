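#' Describe a reciprocal translocation as a terminal-segment exchange
#'
#' A reciprocal translocation that swaps the terminal segment of the focal
#' chromosome arm (length `removed_kb`, carrying the old telomere) for a
#' terminal segment from a donor arm (length `added_kb`, carrying its own
#' telomere). Loci proximal to the breakpoint stay on the focal arm and see
#' their distance to the telomere change by `added_kb - removed_kb`; loci on
#' the removed segment travel with it, keeping their original distance to
#' the telomere they carry along.
#'
#' @param removed_kb length (kb, > 0) of the terminal segment removed from
#'   the focal arm.
#' @param added_kb length (kb, > 0) of the terminal segment appended from
#'   the donor arm.
#' @param label free-text label, e.g. `"IVR-113_XVIR-12"`.
#' @return object of class `terminal_exchange`.
#' @examples
#' terminal_exchange(113, 12, "IVR-113_XVIR-12")
#' @export
terminal_exchange <- function(removed_kb, added_kb, label = NULL) {
  stopifnot(is.numeric(removed_kb), is.numeric(added_kb),
            removed_kb > 0, added_kb > 0)
  structure(list(removed_kb = removed_kb, added_kb = added_kb,
                 label = if (is.null(label))
                   sprintf("exchange_%g_%g", removed_kb, added_kb) else label),
            class = "terminal_exchange")
}

#' @export
print.terminal_exchange <- function(x, ...) {
  cat(sprintf("Terminal exchange %s: -%g kb / +%g kb (shift %+g kb)\n",
              x$label, x$removed_kb, x$added_kb, x$added_kb - x$removed_kb))
  invisible(x)
}

#' Swap removed and added segments of an exchange
#'
#' The inverse translocation: applying an exchange and then its inverse
#' restores the original distance of every locus retained on the focal arm.
#'
#' @param exchange a [terminal_exchange()].
#' @return the inverted `terminal_exchange`.
#' @export
invert_exchange <- function(exchange) {
  terminal_exchange(exchange$added_kb, exchange$removed_kb,
                    paste0(exchange$label, "_inv"))
}

#' Distance to telomere after a terminal-segment exchange
#'
#' A locus at `dist_kb` from the telomere is retained on the focal arm when
#' `dist_kb >= removed_kb` (a locus abutting the breakpoint counts as
#' retained): its new distance is `dist_kb - removed_kb + added_kb`, status
#' `"remapped"`. A locus with `dist_kb < removed_kb` lies on the exchanged
#' segment, which carries its telomere away with it, so its distance is
#' unchanged: status `"moved_with_segment"`.
#'
#' @param dist_kb numeric vector of distances to telomere (kb, >= 0).
#' @param exchange a [terminal_exchange()].
#' @return data frame with columns `old_kb`, `new_kb`, `status`.
#' @examples
#' ex <- terminal_exchange(10, 291)
#' remap_distance(c(10, 57, 117), ex)   # -> 291, 338, 398
#' @export
remap_distance <- function(dist_kb, exchange) {
  stopifnot(inherits(exchange, "terminal_exchange"))
  if (any(dist_kb < 0)) stop("distances must be >= 0")
  retained <- dist_kb >= exchange$removed_kb
  new <- ifelse(retained, dist_kb - exchange$removed_kb + exchange$added_kb,
                dist_kb)
  data.frame(old_kb = dist_kb, new_kb = new,
             status = ifelse(retained, "remapped", "moved_with_segment"))
}

#' Apply a terminal-segment exchange to a locus table
#'
#' Remaps the `distance_kb` of every row via [remap_distance()] and
#' annotates the condition with the exchange label.
#'
#' @param data a data frame with columns `locus` and `distance_kb` (an
#'   efficiency dataset works as-is).
#' @param exchange a [terminal_exchange()].
#' @return `data` with `distance_kb` replaced by post-exchange distances and
#'   added columns `remap_status` and (appended to `condition` if present)
#'   the exchange label.
#' @export
apply_exchange <- function(data, exchange) {
  if (nrow(data) == 0L) return(data)
  rm <- remap_distance(data$distance_kb, exchange)
  data$distance_kb <- rm$new_kb
  data$remap_status <- rm$status
  if ("condition" %in% names(data)) {
    cond <- ifelse(is.na(data$condition) | data$condition == "",
                   exchange$label, paste(data$condition, exchange$label, sep = ";"))
    data$condition <- cond
  }
  data
}
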