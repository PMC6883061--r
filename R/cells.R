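# Cell-list neighbor search. Atoms of set b are binned into cubic cells of
# edge `cutoff`; for every atom of set a only the 27 surrounding cells are
# scanned, so the result is exact with respect to the brute-force O(na*nb)
# definition while scaling linearly for dense systems.

#' All cross-set atom pairs within a distance cutoff
#'
#' @param xa,xb Numeric n x 3 coordinate matrices (Angstrom).
#' @param cutoff Distance cutoff in Angstrom; the boundary is inclusive
#'   (pairs at exactly `cutoff` are returned).
#' @return A list with integer vectors `i` (row index into `xa`), `j` (row
#'   index into `xb`) and numeric `d` (pair distance, Angstrom).
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' p <- neighbor_pairs(a, a, 2.0)
#' @export
neighbor_pairs <- function(xa, xb, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  na <- nrow(xa); nb <- nrow(xb)
  if (na == 0L || nb == 0L)
    return(list(i = integer(0), j = integer(0), d = numeric(0)))
  h <- cutoff
  lo <- pmin(apply(xa, 2, min), apply(xb, 2, min))
  ca <- floor(sweep(xa, 2, lo) / h)
  cb <- floor(sweep(xb, 2, lo) / h)
  M <- max(ca, cb) + 3
  key_of <- function(cc) (cc[, 1] * M + cc[, 2]) * M + cc[, 3]
  bmap <- split(seq_len(nb), key_of(cb))
  amap <- split(seq_len(na), key_of(ca))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out_i <- vector("list", length(amap))
  out_j <- vector("list", length(amap))
  out_d <- vector("list", length(amap))
  cut2 <- cutoff^2
  for (k in seq_along(amap)) {
    ai <- amap[[k]]
    key <- as.numeric(names(amap)[k])
    cz <- key %% M; cy <- (key %/% M) %% M; cx <- key %/% (M * M)
    nkeys <- ((cx + offs[, 1]) * M + (cy + offs[, 2])) * M + (cz + offs[, 3])
    cand <- unlist(bmap[as.character(nkeys)], use.names = FALSE)
    if (!length(cand)) next
    pa <- xa[ai, , drop = FALSE]; pb <- xb[cand, , drop = FALSE]
    d2 <- outer(rowSums(pa^2), rep(1, length(cand))) +
      outer(rep(1, length(ai)), rowSums(pb^2)) - 2 * pa %*% t(pb)
    hit <- which(d2 <= cut2, arr.ind = TRUE)
    if (nrow(hit)) {
      out_i[[k]] <- ai[hit[, 1]]
      out_j[[k]] <- cand[hit[, 2]]
      out_d[[k]] <- sqrt(pmax(d2[hit], 0))
    }
  }
  list(i = unlist(out_i, use.names = FALSE),
       j = unlist(out_j, use.names = FALSE),
       d = unlist(out_d, use.names = FALSE))
}
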