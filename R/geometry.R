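# Small 3D geometry kernel shared by the detectors and the fixture
# generator. Coordinates are plain numeric matrices with columns x,y,z.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

# angle a-b-c at vertex b, degrees
.angle3 <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (.vnorm(u) * .vnorm(v))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

# rotation matrix about unit axis by angle (degrees), Rodrigues form
.rotmat <- function(axis, theta_deg) {
  a <- .unit(axis)
  th <- theta_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rotation taking unit vector u onto unit vector v
.rot_between <- function(u, v) {
  u <- .unit(u); v <- .unit(v)
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any axis perpendicular to u
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- .unit(pracma::cross(u, p))
    return(.rotmat(axis, 180))
  }
  axis <- pracma::cross(u, v)
  s <- .vnorm(axis)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

# any unit vector perpendicular to v
.perp_unit <- function(v) {
  p <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(pracma::cross(v, p))
}

# random rotation matrix from 3 uniforms (Arvo's method is overkill; a
# QR-based draw is uniform enough for posing fixtures)
.random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# ---------------------------------------------------------------------------
# Fixed-radius cross-set pair search.
#
# close_pairs() is the production backend: uniform spatial binning with cell
# size = cutoff, exact (no approximation) because all 27 neighbor cells are
# scanned. close_pairs_brute() is the quadratic reference the binned search
# must agree with exactly.

#' All cross-set atom pairs within a distance cutoff
#'
#' Returns every pair (i, j) with \code{i} indexing rows of \code{a},
#' \code{j} rows of \code{b}, whose Euclidean distance is <= cutoff.
#' The \code{cells} method bins coordinates into a uniform grid with cell
#' size equal to the cutoff and scans the 27 neighboring cells, which is
#' exactly equivalent to the brute-force all-pairs scan.
#'
#' @param a,b numeric matrices with 3 columns (x, y, z).
#' @param cutoff distance cutoff in Angstrom.
#' @param method "cells" (default) or "brute".
#' @return data frame with columns i, j, d (sorted by i then j).
#' @export
close_pairs <- function(a, b, cutoff, method = c("cells", "brute")) {
  method <- match.arg(method)
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  }
  if (method == "brute") return(close_pairs_brute(a, b, cutoff))

  cell <- cutoff
  key <- function(m) {
    ix <- floor(m / cell)
    paste(ix[, 1], ix[, 2], ix[, 3], sep = ",")
  }
  kb <- key(b)
  bmap <- split(seq_len(nrow(b)), kb)
  ia <- floor(a / cell)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  res_i <- vector("list", nrow(a))
  res_j <- vector("list", nrow(a))
  res_d <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    keys <- paste(ia[i, 1] + off[, 1], ia[i, 2] + off[, 2],
                  ia[i, 3] + off[, 3], sep = ",")
    cand <- unlist(bmap[keys], use.names = FALSE)
    if (!length(cand)) next
    dv <- sqrt(colSums((t(b[cand, , drop = FALSE]) - a[i, ])^2))
    keep <- dv <= cutoff
    if (any(keep)) {
      res_i[[i]] <- rep.int(i, sum(keep))
      res_j[[i]] <- cand[keep]
      res_d[[i]] <- dv[keep]
    }
  }
  out <- data.frame(i = unlist(res_i), j = unlist(res_j), d = unlist(res_d))
  if (!nrow(out)) return(data.frame(i = integer(), j = integer(),
                                    d = numeric()))
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname close_pairs
#' @export
close_pairs_brute <- function(a, b, cutoff) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  out <- data.frame(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]),
                    d = sqrt(d2[hit]))
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}
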