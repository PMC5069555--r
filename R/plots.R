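# Lightweight base-graphics views of the main summaries. All plots are
# derived from the same data frames the writers emit, so headless tests
# never need a graphics device.

#' Plot tail-length histograms per composition class
#'
#' @param hist A `tail_histograms` object from [tail_length_histogram()].
#' @param classes Classes to draw (default: all present).
#' @return Invisibly, the counts table drawn.
#' @export
plot_tail_histogram <- function(hist, classes = NULL) {
  counts <- hist$counts
  if (!nrow(counts)) { plot.new(); return(invisible(counts)) }
  cls <- classes %||% unique(counts$class)
  old <- par(mfrow = c(1, length(cls)), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (cl in cls) {
    d <- counts[counts$class == cl, ]
    lens <- seq(1, max(c(d$length, 4)))
    y <- setNames(numeric(length(lens)), lens)
    y[as.character(d$length)] <- d$count
    barplot(y, main = cl, xlab = "3' tail length (nt)", ylab = "reads",
            col = if (cl == "U+") "firebrick" else "grey60")
  }
  invisible(counts)
}

#' Plot a scaled gene-body coverage heat map
#'
#' @param mat Matrix from [scaled_coverage()] (genes x bins, rows in
#'   `[0, 1]`).
#' @return Invisibly, the matrix.
#' @export
plot_scaled_coverage <- function(mat) {
  if (!nrow(mat)) { plot.new(); return(invisible(mat)) }
  image(t(mat[rev(seq_len(nrow(mat))), , drop = FALSE]),
        col = hcl.colors(64, "YlOrRd", rev = TRUE), axes = FALSE,
        xlab = "position in mature RNA (5' -> 3', % of length)",
        ylab = "")
  axis(1, at = c(0, 0.5, 1), labels = c("0%", "50%", "100%"))
  invisible(mat)
}

#' Plot a TSS metagene profile (sense, antisense, optional overlay)
#'
#' @param metagene A `metagene_profile` from [tss_metagene()].
#' @return Invisibly, the profile data frame.
#' @export
plot_metagene <- function(metagene) {
  p <- metagene$profile
  ylim <- range(c(p$sense, p$antisense), 0)
  plot(p$offset, moving_average(p$sense, metagene$smooth), type = "l",
       col = "firebrick", lwd = 2, ylim = ylim,
       xlab = "offset from TSS (nt, upstream negative)",
       ylab = "U+ read 3' ends")
  lines(p$offset, moving_average(p$antisense, metagene$smooth),
        col = "steelblue", lwd = 2)
  if (!is.null(p$overlay)) {
    ov <- p$overlay
    if (max(ov, na.rm = TRUE) > 0)
      ov <- ov / max(ov, na.rm = TRUE) * max(ylim)
    lines(p$offset, ov, col = "grey40", lty = 2)
  }
  abline(v = 0, col = "grey70")
  legend("topright", bty = "n", lwd = 2, lty = c(1, 1, 2),
         col = c("firebrick", "steelblue", "grey40"),
         legend = c("sense", "antisense", "overlay"))
  invisible(p)
}
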