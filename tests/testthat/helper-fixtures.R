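# Shared fixtures: tiny meshes and random field generators, built in code.

# flat strip of n side-by-side unit-ish triangles with controllable areas:
# triangle i spans x in [i-1, i] with height heights[i] (area = heights[i]/2)
strip_mesh <- function(heights) {
  n <- length(heights)
  pts <- rbind(cbind(seq(0, n), 0, 0),
               cbind(seq_len(n) - 0.5, heights, 0))
  tris <- cbind(seq_len(n) - 1L, seq_len(n), n + seq_len(n))
  surface_mesh(pts, tris)
}

# random vector3 WSS series on ne elements over a uniform window
random_wss_series <- function(ne, n_t = 32L, period = 1) {
  w <- uniform_window(period, n_t)
  vals <- array(stats::rnorm(n_t * ne * 3L), dim = c(n_t, ne, 3L))
  field_series(vals, "vector3", "element", w, "Pa")
}

# random symmetric tensor series (uniform window, 1 sample repeated)
random_tensor <- function() stats::rnorm(6L, sd = 5)

# random 3D rotation matrix (QR of a random Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# apply a rotation R to a 6-component symmetric tensor (xx,yy,zz,xy,xz,yz)
rotate_sym6 <- function(s6, R) {
  S <- matrix(c(s6[1], s6[4], s6[5],
                s6[4], s6[2], s6[6],
                s6[5], s6[6], s6[3]), 3L, 3L)
  Sr <- R %*% S %*% t(R)
  c(Sr[1, 1], Sr[2, 2], Sr[3, 3], Sr[1, 2], Sr[1, 3], Sr[2, 3])
}

# brute-force robust maximum: sort descending, drop the minimal prefix whose
# cumulative area reaches omit * total, return the max of the rest
brute_robust_max <- function(values, areas, omit) {
  if (omit == 0) return(max(values))
  ord <- order(values, decreasing = TRUE)
  v <- values[ord]; a <- areas[ord]
  target <- omit * sum(areas)
  cum <- cumsum(a)
  k <- which(cum >= target)[1L]
  if (is.na(k) || k >= length(v)) return(v[length(v)])
  max(v[(k + 1L):length(v)])
}

# brute-force area-exceedance percentage
brute_area_fraction <- function(values, areas, bound, direction) {
  hit <- if (direction == "above") values > bound else values < bound
  100 * sum(areas[hit]) / sum(areas)
}

# scalar trapezoid (independent of the package's internal integrator)
trapz_ref <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

n_elements_for_test <- function(mesh)
  if (!is.null(mesh$triangles)) nrow(mesh$triangles) else nrow(mesh$tets)

# wrap a (n_t x ne) axial scalar signal as an element vector3 series along x
axial_series <- function(sig, window, ne = 1L) {
  vals <- array(0, dim = c(length(window$sample_times), ne, 3L))
  vals[, , 1L] <- sig
  field_series(vals, "vector3", "element", window, "Pa")
}
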