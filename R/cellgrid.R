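# Cell-list spatial decomposition. Space is a regular grid of subdomains
# ("cells", unrelated to biological cells); each cell is at least one cutoff
# wide on every axis where more than one cell fits, so all in-cutoff pairs
# are found within a cell (Force Self) or between neighboring cells (Force
# Pair). Neighbor cell pairs are enumerated once per grid geometry,
# including periodic wraps, with deduplication so degenerate 1-2 cell axes
# are not double counted.

#' Build (or fetch) the cell grid of a universe
#'
#' The grid partitions each axis into `max(1, floor(L / cutoff))` cells.
#' When fewer than one cutoff fits an axis, the whole axis is a single cell
#' and all its pairs are handled by the self task. The grid is cached and
#' rebuilt only when the geometry or cutoff changes.
#'
#' @param u a [universe]
#' @return a `cell_grid` list: `counts`, `cell_size`, and the unordered
#'   neighbor cell-pair arrays `pair_a`, `pair_b` (0-based cell indices)
#' @export
build_cell_grid <- function(u) {
  key <- c(u$dims, u$cutoff)
  if (!is.null(u$grid) && identical(u$grid$key, key)) return(u$grid)
  per <- u$boundary == "periodic"
  if (any(per) && u$cutoff > min(u$dims[per])) {
    stop("cutoff exceeds a periodic domain extent; no valid decomposition")
  }
  counts <- pmax(1L, as.integer(floor(u$dims / u$cutoff)))
  cell_size <- u$dims / counts
  nc <- prod(counts)
  # half set of 13 neighbor offsets (plus self handled separately)
  offs <- list()
  for (dz in 0:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && (dy < 0 || (dy == 0 && dx <= 0))) next
    offs[[length(offs) + 1]] <- c(dx, dy, dz)
  }
  # coordinates of every cell
  ix <- rep.int(0:(counts[1] - 1L), counts[2] * counts[3])
  iy <- rep.int(rep(0:(counts[2] - 1L), each = counts[1]), counts[3])
  iz <- rep(0:(counts[3] - 1L), each = counts[1] * counts[2])
  keys_seen <- numeric(0)
  pa <- integer(0); pb <- integer(0)
  for (off in offs) {
    jx <- ix + off[1]; jy <- iy + off[2]; jz <- iz + off[3]
    ok <- rep(TRUE, nc)
    co <- list(jx, jy, jz)
    for (ax in 1:3) {
      n <- counts[ax]
      if (per[ax]) {
        co[[ax]] <- co[[ax]] %% n
      } else {
        ok <- ok & co[[ax]] >= 0 & co[[ax]] < n
      }
    }
    a <- ix + counts[1] * (iy + counts[2] * iz)
    b <- co[[1]] + counts[1] * (co[[2]] + counts[2] * co[[3]])
    ok <- ok & a != b     # wrap onto self on a 1-cell axis: already in self task
    a <- a[ok]; b <- b[ok]
    key2 <- pmin(a, b) * nc + pmax(a, b)
    new <- !(key2 %in% keys_seen) & !duplicated(key2)
    keys_seen <- c(keys_seen, key2[new])
    pa <- c(pa, a[new]); pb <- c(pb, b[new])
  }
  u$grid <- list(key = key, counts = counts, cell_size = cell_size,
                 n_cells = nc, pair_a = pa, pair_b = pb)
  class(u$grid) <- "cell_grid"
  u$grid
}

# 0-based cell index of each given slot
.cell_of <- function(u, slots, grid) {
  idx <- integer(length(slots))
  ci <- list()
  for (ax in 1:3) {
    k <- as.integer(floor(u$pos[slots, ax] / grid$cell_size[ax]))
    ci[[ax]] <- pmin(pmax(k, 0L), grid$counts[ax] - 1L)
  }
  ci[[1]] + grid$counts[1] * (ci[[2]] + grid$counts[2] * ci[[3]])
}

#' Ordered projections of a cell's particles toward a neighbor cell
#'
#' The Sort task of the Force stage: particles of a cell are ordered by the
#' projection of their position onto the axis between a cell pair, enabling
#' pruning of cross-cell pairs separated by more than the cutoff along that
#' axis. Ties are broken by particle id (stable order).
#'
#' @param u a [universe]
#' @param slots integer particle slots in the cell (internal indices)
#' @param axis_vec direction vector from the cell to its neighbor
#' @return slots reordered by ascending projection, ties by id
#' @export
sort_cell <- function(u, slots, axis_vec) {
  if (!length(slots)) return(integer(0))
  proj <- as.vector(u$pos[slots, , drop = FALSE] %*% (axis_vec / sqrt(sum(axis_vec^2))))
  slots[order(proj, u$id[slots])]
}

# enumerate all unordered particle pairs with minimum-image distance < rmax
# (strict), via the cell decomposition; returns slot indices, displacement
# components (j minus i, minimum image) and distances
enumerate_pairs <- function(u, rmax = u$cutoff) {
  grid <- build_cell_grid(u)
  live <- .live_slots(u)
  out0 <- list(ii = integer(0), jj = integer(0),
               dx = numeric(0), dy = numeric(0), dz = numeric(0), r = numeric(0))
  if (length(live) < 2) return(out0)
  ci <- .cell_of(u, live, grid)
  ord <- order(ci, u$id[live])
  live <- live[ord]; ci <- ci[ord]
  memb <- split(live, factor(ci, levels = 0:(grid$n_cells - 1L)))
  len <- lengths(memb)
  ii_l <- list(); jj_l <- list(); n_chunk <- 0L
  # Force Self: pairs within one cell (only occupied cells)
  for (c1 in which(len >= 2L)) {
    m <- memb[[c1]]
    tpl <- .pair_template(length(m))
    n_chunk <- n_chunk + 1L
    ii_l[[n_chunk]] <- m[tpl$a]; jj_l[[n_chunk]] <- m[tpl$b]
  }
  # Force Pair: pairs between neighboring cells (both occupied)
  active <- which(len[grid$pair_a + 1L] > 0L & len[grid$pair_b + 1L] > 0L)
  for (q in active) {
    A <- memb[[grid$pair_a[q] + 1L]]
    B <- memb[[grid$pair_b[q] + 1L]]
    n_chunk <- n_chunk + 1L
    ii_l[[n_chunk]] <- rep(A, each = length(B))
    jj_l[[n_chunk]] <- rep.int(B, length(A))
  }
  if (!n_chunk) return(out0)
  ii <- unlist(ii_l, use.names = FALSE)
  jj <- unlist(jj_l, use.names = FALSE)
  d <- u$pos[jj, , drop = FALSE] - u$pos[ii, , drop = FALSE]
  for (ax in 1:3) {
    if (u$boundary[ax] == "periodic") {
      L <- u$dims[ax]
      d[, ax] <- d[, ax] - L * round(d[, ax] / L)
    }
  }
  r2 <- d[, 1]^2 + d[, 2]^2 + d[, 3]^2
  keep <- r2 < rmax^2
  list(ii = ii[keep], jj = jj[keep],
       dx = d[keep, 1], dy = d[keep, 2], dz = d[keep, 3],
       r = sqrt(r2[keep]))
}

# cached unordered-pair index templates, one per group size
.pair_tpl_cache <- new.env(parent = emptyenv())
.pair_template <- function(m) {
  key <- as.character(m)
  t <- .pair_tpl_cache[[key]]
  if (is.null(t)) {
    a <- rep.int(seq_len(m - 1L), (m - 1L):1L)
    b <- unlist(lapply(seq_len(m - 1L), function(k) (k + 1L):m), use.names = FALSE)
    t <- list(a = a, b = b)
    .pair_tpl_cache[[key]] <- t
  }
  t
}
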