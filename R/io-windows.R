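#' Tile chromosomes into analysis windows
#'
#' Windows are 0-based half-open intervals.  By default chromosomes are tiled
#' with non-overlapping windows of `width` bases; setting `step < width`
#' produces genuinely sliding (overlapping) windows.  A trailing window
#' shorter than `width` is kept but flagged `partial`; windowed statistics
#' exclude flagged windows by default so that short windows cannot bias the
#' genome-wide distribution.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param width window width in bp (default 500 kb).
#' @param step distance between successive window starts (default `width`,
#'   i.e. non-overlapping tiles).
#' @return A data frame of class `window_spec` with columns `chrom`, `start`,
#'   `end`, `partial`.
#' @examples
#' make_windows(c(chr1 = 1.2e6), width = 5e5)
#' @export
make_windows <- function(chrom_lengths, width = 5e5, step = width) {
  stopifnot(width >= 1, step >= 1, !is.null(names(chrom_lengths)))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    ends <- pmin(starts + width, len)
    data.frame(chrom = ch, start = starts, end = ends,
               partial = (ends - starts) < width,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "width") <- width
  attr(out, "step") <- step
  class(out) <- c("window_spec", "data.frame")
  out
}

#' Assign 1-based site positions to windows
#'
#' A site at VCF position `p` (1-based) occupies 0-based coordinate `p - 1`
#' and falls in a window `[start, end)` iff `start <= p - 1 < end`.  For
#' non-overlapping tiles of width `w` this is the window starting at
#' `((p - 1) %/% w) * w`.  With sliding windows a site may be assigned to
#' several windows.
#'
#' @param chrom,pos site chromosome labels and 1-based positions.
#' @param windows a window table from [make_windows()].
#' @return A list with one integer vector of site indices per window row.
#' @export
assign_windows <- function(chrom, pos, windows) {
  p0 <- pos - 1
  lapply(seq_len(nrow(windows)), function(i) {
    which(chrom == windows$chrom[i] &
            p0 >= windows$start[i] & p0 < windows$end[i])
  })
}

#' Write windows and attached statistics as BED
#'
#' Columns: chrom, start, end, Hp, ZHp, flag (`partial`, `low_snp`, `sweep`
#' or `.`), 0-based half-open.  Windows violating `end > start` are rejected.
#'
#' @param windows a window table, optionally carrying `hp`, `zhp`, `flag`
#'   columns (as produced by [window_hp()] / [call_sweep_windows()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  if (any(windows$end <= windows$start))
    stop("window with end <= start rejected", call. = FALSE)
  hp <- if ("hp" %in% names(windows)) windows$hp else NA_real_
  zhp <- if ("zhp" %in% names(windows)) windows$zhp else NA_real_
  flag <- if ("flag" %in% names(windows)) windows$flag
          else ifelse(windows$partial, "partial", ".")
  df <- data.frame(windows$chrom, format(windows$start, scientific = FALSE, trim = TRUE),
                   format(windows$end, scientific = FALSE, trim = TRUE),
                   ifelse(is.na(hp), ".", formatC(hp, digits = 10, format = "g")),
                   ifelse(is.na(zhp), ".", formatC(zhp, digits = 10, format = "g")),
                   flag)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a window BED written by [write_windows_bed()]
#'
#' @param path BED file path.
#' @return A window table with `hp`, `zhp`, `flag` columns (`NA` where the
#'   file holds `.`).
#' @export
read_windows_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "hp", "zhp", "flag"),
                          na.strings = ".", colClasses = c("character", "numeric",
                          "numeric", "numeric", "numeric", "character"))
  df$flag[is.na(df$flag)] <- "."
  df$partial <- df$flag == "partial"
  class(df) <- c("window_spec", "data.frame")
  df
}
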