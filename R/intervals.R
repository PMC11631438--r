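# Interval arithmetic on 0-based half-open (chrom, start, end) tibbles.
# The per-chromosome kernels work on sorted disjoint numeric vectors; all
# operations reduce their inputs first, so callers can pass arbitrary sets.

iv_empty <- function() {
  tibble(chrom = character(), start = double(), end = double())
}

iv_validate <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$start >= x$end)) abort("intervals must satisfy start < end")
  invisible(x)
}

# merge overlapping/adjacent intervals; returns list(start, end), sorted
merge_iv <- function(s, e) {
  if (length(s) == 0) return(list(start = double(), end = double()))
  ord <- order(s, e)
  s <- s[ord]; e <- e[ord]
  cme <- cummax(e)
  newgrp <- c(TRUE, s[-1] > cme[-length(cme)])
  g <- cumsum(newgrp)
  list(start = s[newgrp],
       end = as.double(tapply(e, g, max)))
}

# intersection of two merged interval lists (two-pointer sweep)
intersect_iv <- function(a, b) {
  out_s <- double(); out_e <- double()
  i <- 1L; j <- 1L
  while (i <= length(a$start) && j <= length(b$start)) {
    lo <- max(a$start[i], b$start[j])
    hi <- min(a$end[i], b$end[j])
    if (lo < hi) { out_s <- c(out_s, lo); out_e <- c(out_e, hi) }
    if (a$end[i] <= b$end[j]) i <- i + 1L else j <- j + 1L
  }
  list(start = out_s, end = out_e)
}

# a minus b, both merged
setdiff_iv <- function(a, b) {
  out_s <- double(); out_e <- double()
  j <- 1L
  for (i in seq_along(a$start)) {
    cur <- a$start[i]
    while (j <= length(b$start) && b$end[j] <= cur) j <- j + 1L
    k <- j
    while (k <= length(b$start) && b$start[k] < a$end[i]) {
      if (b$start[k] > cur) { out_s <- c(out_s, cur); out_e <- c(out_e, b$start[k]) }
      cur <- max(cur, b$end[k])
      k <- k + 1L
    }
    if (cur < a$end[i]) { out_s <- c(out_s, cur); out_e <- c(out_e, a$end[i]) }
  }
  list(start = out_s, end = out_e)
}

# split a tibble into per-chrom merged kernels
iv_kernels <- function(x) {
  chroms <- unique(x$chrom)
  out <- vector("list", length(chroms))
  names(out) <- chroms
  for (ch in chroms) {
    sel <- x$chrom == ch
    out[[ch]] <- merge_iv(x$start[sel], x$end[sel])
  }
  out
}

iv_from_kernels <- function(ks) {
  ks <- ks[order(names(ks))]
  n <- map_int(ks, ~ length(.x$start))
  if (sum(n) == 0) return(iv_empty())
  tibble(
    chrom = rep(names(ks), n),
    start = unlist(map(ks, "start"), use.names = FALSE),
    end = unlist(map(ks, "end"), use.names = FALSE)
  )
}

iv_binop <- function(a, b, kernel_fun, keep_a_only = FALSE, keep_b_only = FALSE) {
  ka <- iv_kernels(a)
  kb <- iv_kernels(b)
  chroms <- union(names(ka), names(kb))
  empty <- list(start = double(), end = double())
  out <- setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) {
    xa <- ka[[ch]] %||% empty
    xb <- kb[[ch]] %||% empty
    out[[ch]] <- kernel_fun(xa, xb)
  }
  iv_from_kernels(out)
}

# Merge overlapping/adjacent intervals.
iv_reduce <- function(x) {
  if (nrow(x) == 0) return(iv_empty())
  iv_validate(x)
  iv_from_kernels(iv_kernels(x))
}

iv_union <- function(a, b) iv_reduce(bind_rows(a, b))

iv_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(iv_empty())
  iv_binop(a, b, intersect_iv)
}

iv_setdiff <- function(a, b) {
  if (nrow(a) == 0) return(iv_empty())
  if (nrow(b) == 0) return(iv_reduce(a))
  iv_binop(a, b, setdiff_iv)
}

iv_total_bp <- function(x) if (nrow(x) == 0) 0 else sum(x$end - x$start)

# TRUE for each (chrom, pos) lying inside the interval set.
iv_contains <- function(x, chrom, pos) {
  if (nrow(x) == 0 || length(pos) == 0) return(rep(FALSE, length(pos)))
  ks <- iv_kernels(x)
  out <- rep(FALSE, length(pos))
  for (ch in names(ks)) {
    sel <- which(chrom == ch)
    if (length(sel) == 0) next
    k <- findInterval(pos[sel], ks[[ch]]$start)
    out[sel] <- k >= 1 & pos[sel] < ks[[ch]]$end[pmax(k, 1)]
  }
  out
}

#' Define an autosomal genome layout
#'
#' A layout is the coordinate system the simulator and the accessible-region
#' geometry operate on: an ordered set of autosomes with physical lengths and
#' a (constant) recombination rate in cM/Mb.
#'
#' @param n_chrom Number of autosomes.
#' @param length_bp Length of each autosome in bp (recycled).
#' @param cm_per_mb Recombination rate in centimorgans per megabase (recycled).
#' @return A tibble with columns `chrom`, `length_bp`, `cm_per_mb`.
#' @examples
#' genome_layout()                      # 2 x 100 Mb at 1 cM/Mb
#' genome_layout(3, 5e7, cm_per_mb = 2)
#' @export
genome_layout <- function(n_chrom = 2, length_bp = 1e8, cm_per_mb = 1) {
  stopifnot(n_chrom >= 1, all(length_bp > 0), all(cm_per_mb >= 0))
  tibble(
    chrom = paste0("chr", seq_len(n_chrom)),
    length_bp = rep_len(as.double(length_bp), n_chrom),
    cm_per_mb = rep_len(as.double(cm_per_mb), n_chrom)
  )
}

layout_total_bp <- function(layout) sum(layout$length_bp)

layout_intervals <- function(layout) {
  tibble(chrom = layout$chrom, start = 0, end = layout$length_bp)
}
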