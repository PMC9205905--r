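# Pairwise Forster geometry in the point-dipole approximation. The transfer
# rate proxy is k ∝ V²Θ with V the dipole–dipole coupling
#   V ≈ μD·μA / r³ − 3 (r·μD)(r·μA) / r⁵
#     = μD μA (cosθT − 3 cosθD cosθA) / r³,
# and the orientation factor κ² = (cosθT − 3 cosθD cosθA)² ∈ [0, 4]. Θ is held
# at a constant (overlap_factor_default): all couplings/weights are relative.

check_unit <- function(v, name) {
  if (length(v) != 3L || !all(is.finite(v)))
    stop(name, " must be a finite 3-vector")
  if (abs(sqrt(sum(v^2)) - 1) > 1e-6)
    stop(name, " must be a unit vector (|", name, "| = 1 within 1e-6)")
  invisible(v)
}

#' Orientation factor kappa-squared for one donor/acceptor pair
#'
#' `(cos_theta_T - 3 cos_theta_D cos_theta_A)^2` with
#' `cos_theta_T = mu_d . mu_a`, `cos_theta_D = mu_d . r_hat`,
#' `cos_theta_A = mu_a . r_hat`. Always in `[0, 4]`; the isotropic average is
#' 2/3.
#'
#' @param mu_d,mu_a Unit transition-dipole directions (|.| = 1 within 1e-6).
#' @param r_vec Donor-to-acceptor centre separation vector in Angstrom
#'   (non-zero).
#' @return Dimensionless scalar in `[0, 4]`.
#' @export
kappa_squared <- function(mu_d, mu_a, r_vec) {
  check_unit(mu_d, "mu_d"); check_unit(mu_a, "mu_a")
  r <- sqrt(sum(r_vec^2))
  if (!is.finite(r) || r <= 0) stop("coincident centroids: |r_vec| must be > 0")
  rh <- r_vec / r
  ct <- sum(mu_d * mu_a)
  cd <- sum(mu_d * rh)
  ca <- sum(mu_a * rh)
  (ct - 3 * cd * ca)^2
}

# Vectorised kappa² over row-matched matrices of unit dipoles; r_hat is a
# single unit vector or a row-matched matrix.
kappa_squared_vec <- function(Md, Ma, rhat) {
  ct <- rowSums(Md * Ma)
  if (is.matrix(rhat)) {
    cd <- rowSums(Md * rhat); ca <- rowSums(Ma * rhat)
  } else {
    cd <- Md %*% rhat; ca <- Ma %*% rhat
  }
  as.numeric((ct - 3 * cd * ca)^2)
}

#' Relative dipole-dipole coupling
#'
#' The point-dipole coupling in either its vector form
#' (`mu_d.mu_a/r^3 - 3(r.mu_d)(r.mu_a)/r^5`) or the equivalent cosine form
#' (`mag_d mag_a (cos_theta_T - 3 cos_theta_D cos_theta_A) / r^3`). The two
#' forms agree to machine precision; both are exposed so the identity can be
#' checked. Units are relative (magnitudes default to 1).
#'
#' @param mu_d,mu_a Unit dipole directions.
#' @param r_vec Separation vector, Angstrom.
#' @param mag_d,mag_a Relative dipole magnitudes (> 0).
#' @param form `"cosine"` or `"vector"`.
#' @return Signed relative coupling (Angstrom^-3 scale).
#' @export
dipole_coupling <- function(mu_d, mu_a, r_vec, mag_d = 1, mag_a = 1,
                            form = c("cosine", "vector")) {
  form <- match.arg(form)
  check_unit(mu_d, "mu_d"); check_unit(mu_a, "mu_a")
  r <- sqrt(sum(r_vec^2))
  if (!is.finite(r) || r <= 0) stop("coincident centroids: |r_vec| must be > 0")
  if (form == "vector") {
    md <- mag_d * mu_d; ma <- mag_a * mu_a
    sum(md * ma) / r^3 - 3 * sum(r_vec * md) * sum(r_vec * ma) / r^5
  } else {
    rh <- r_vec / r
    mag_d * mag_a *
      (sum(mu_d * mu_a) - 3 * sum(mu_d * rh) * sum(mu_a * rh)) / r^3
  }
}

#' Full Forster geometry of one donor/acceptor chromophore pair
#'
#' @param donor,acceptor `chromophore` objects with assigned dipoles and
#'   distinct centroids.
#' @param overlap_factor Spectral overlap constant (default
#'   [overlap_factor_default]).
#' @return One-row data.frame: `donor_id`, `acceptor_id`, cylinder
#'   annotations, separation vector (`rx`, `ry`, `rz`), `r`, the three
#'   cosines, `kappa_sq`, signed `v_rel`, rate-proxy `weight` (kappa_sq/r^6),
#'   and `overlap_factor`.
#' @export
pair_geometry <- function(donor, acceptor,
                          overlap_factor = overlap_factor_default) {
  for (ch in list(donor, acceptor))
    if (is.null(ch$dipole))
      stop("missing dipole for chromophore ", ch$id$rendered)
  r_vec <- acceptor$centroid - donor$centroid
  r <- sqrt(sum(r_vec^2))
  if (!is.finite(r) || r <= 0)
    stop("coincident centroids: ", donor$id$rendered, " and ",
         acceptor$id$rendered)
  rh <- r_vec / r
  mu_d <- donor$dipole$direction; mu_a <- acceptor$dipole$direction
  ct <- sum(mu_d * mu_a); cd <- sum(mu_d * rh); ca <- sum(mu_a * rh)
  kap <- ct - 3 * cd * ca
  mags <- donor$dipole$magnitude * acceptor$dipole$magnitude
  data.frame(
    donor_id = donor$id$rendered, acceptor_id = acceptor$id$rendered,
    donor_cylinder = donor$id$cylinder, acceptor_cylinder = acceptor$id$cylinder,
    rx = r_vec[1], ry = r_vec[2], rz = r_vec[3], r = r,
    cos_theta_T = ct, cos_theta_D = cd, cos_theta_A = ca,
    kappa_sq = kap^2,
    v_rel = mags * kap / r^3,
    weight = kap^2 / r^6,
    overlap_factor = overlap_factor,
    stringsAsFactors = FALSE)
}

#' All chromophore pairs within a distance cutoff
#'
#' Every unordered pair with centre-to-centre distance `r <= cutoff`, emitted
#' once with the lexicographically smaller rendered ID as donor, sorted by
#' descending rate-proxy weight (ties by donor then acceptor ID). Chromophores
#' flagged incomplete are excluded. The default cutoff of 35 Angstrom spans
#' the longest inter-cylinder bridging distances seen in phycobilisome cores.
#'
#' @param chroms List of `chromophore` objects.
#' @param cutoff Distance gate in Angstrom (> 0, default 35).
#' @param overlap_factor Spectral overlap constant.
#' @return Pair table data.frame (zero rows when nothing is in range).
#' @export
all_pairs <- function(chroms, cutoff = 35,
                      overlap_factor = overlap_factor_default) {
  stopifnot(cutoff > 0)
  chroms <- Filter(function(ch) !isTRUE(ch$incomplete), chroms)
  n <- length(chroms)
  empty <- pair_table_skeleton()
  if (n < 2L) return(empty)

  cent <- t(vapply(chroms, function(ch) ch$centroid, numeric(3)))
  d <- as.matrix(stats::dist(cent))
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (d[i, j] > cutoff) next
    ci <- chroms[[i]]; cj <- chroms[[j]]
    if (ci$id$rendered <= cj$id$rendered)
      rows[[length(rows) + 1L]] <- pair_geometry(ci, cj, overlap_factor)
    else
      rows[[length(rows) + 1L]] <- pair_geometry(cj, ci, overlap_factor)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$weight, out$donor_id, out$acceptor_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

pair_table_skeleton <- function() {
  data.frame(donor_id = character(), acceptor_id = character(),
             donor_cylinder = character(), acceptor_cylinder = character(),
             rx = numeric(), ry = numeric(), rz = numeric(), r = numeric(),
             cos_theta_T = numeric(), cos_theta_D = numeric(),
             cos_theta_A = numeric(), kappa_sq = numeric(),
             v_rel = numeric(), weight = numeric(),
             overlap_factor = numeric(), stringsAsFactors = FALSE)
}

#' Monte-Carlo isotropic average of kappa-squared
#'
#' Mean of the orientation factor over `n` independent pairs of
#' uniform-on-sphere dipole directions at a fixed separation vector. Converges
#' to the freely rotating limit of 2/3 with standard error of order
#' `n^(-1/2)`. Sampling draws 3D standard normals and normalises (unbiased on
#' the sphere, seedable).
#'
#' @param n Number of orientation pairs (>= 1).
#' @param seed Integer seed; the same seed reproduces the result exactly.
#' @return Scalar mean of kappa-squared.
#' @export
isotropic_kappa_mean <- function(n, seed = 1L) {
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  withr::with_seed(as.integer(seed), {
    Md <- matrix(stats::rnorm(3L * n), ncol = 3L)
    Ma <- matrix(stats::rnorm(3L * n), ncol = 3L)
    Md <- Md / sqrt(rowSums(Md^2))
    Ma <- Ma / sqrt(rowSums(Ma^2))
    mean(kappa_squared_vec(Md, Ma, c(0, 0, 1)))
  })
}
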