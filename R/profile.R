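#' Sliding-window Hscore profile of an element class
#'
#' Computes the Hscore of the elements themselves (offset 0) and of the
#' tracks obtained by shifting every element by k times its own length,
#' k in -max_k..+max_k (see [shift_track()]).  The element class is then
#' called hotspot / hot region / not significant from the offset-0 score
#' and its two immediate neighbours via [classify_structure()].
#'
#' @param catalog a [bp_catalog()].
#' @param track a [bp_track()].
#' @param genome a [bp_genome()].
#' @param n_total total breakpoints defining \eqn{P_u}; defaults to
#'   \code{nrow(catalog)}.
#' @param max_k maximum shift multiple (default 8).
#' @return An object of class \code{"hscore_profile"}: list with
#'   \code{element_class}, \code{offsets}, \code{results} (one [hscore()]
#'   per offset), \code{table} (data.frame offset/ni/Li/hscore) and
#'   \code{call_structure} (the [classify_structure()] result).
#' @export
hscore_profile <- function(catalog, track, genome,
                           n_total = nrow(catalog), max_k = 8) {
  offsets <- seq(-max_k, max_k)
  results <- lapply(offsets, function(k) {
    tr <- if (k == 0) track else
      suppressMessages(shift_track(track, k, genome))
    hscore(catalog, tr, genome, n_total = n_total)
  })
  names(results) <- as.character(offsets)
  tab <- data.frame(
    element_class = element_class(track),
    offset = offsets,
    ni = vapply(results, `[[`, numeric(1), "ni"),
    Li = vapply(results, `[[`, numeric(1), "Li"),
    hscore = vapply(results, `[[`, numeric(1), "hscore"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  call <- classify_structure(results[["0"]]$hscore,
                             results[["-1"]]$hscore,
                             results[["1"]]$hscore)
  structure(list(element_class = element_class(track),
                 offsets = offsets, results = results, table = tab,
                 call_structure = call),
            class = "hscore_profile")
}

#' @export
print.hscore_profile <- function(x, ...) {
  cat(sprintf("Hscore profile [%s], offsets %+d..%+d: %s\n",
              x$element_class, min(x$offsets), max(x$offsets),
              x$call_structure$verdict))
  print(x$table[, c("offset", "ni", "Li", "hscore")], row.names = FALSE)
  invisible(x)
}

#' Plot an Hscore profile
#'
#' Hscore against window offset with the hotspotness cutoff drawn as a
#' horizontal dashed line.
#'
#' @param x an [hscore_profile()].
#' @param h_min cutoff line (default 3).
#' @param cap plotting value for infinite scores.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hscore_profile <- function(x, h_min = 3, cap = 350, ...) {
  h <- pmin(x$table$hscore, cap)
  graphics::plot(x$table$offset, h, type = "b", pch = 19,
                 xlab = "window offset (element lengths)",
                 ylab = "Hscore",
                 main = sprintf("%s (%s)", x$element_class,
                                x$call_structure$verdict), ...)
  graphics::abline(h = h_min, lty = 2, col = "red")
  invisible(x)
}

#' @rdname hscore_profile
#' @param profile an \code{hscore_profile}.
#' @param path optional TSV output path.
#' @export
profile_table <- function(profile, path = NULL) {
  if (!is.null(path))
    utils::write.table(profile$table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  profile$table
}
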