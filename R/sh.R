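#' Number of even-order real spherical-harmonic coefficients
#'
#' An antipodally symmetric spherical function (such as a fiber orientation
#' distribution) only has even-order terms; through order `lmax` there are
#' `(lmax + 1) * (lmax + 2) / 2` of them.
#'
#' @param lmax Even nonnegative integer, maximum spherical-harmonic order.
#' @return Integer number of coefficients.
#' @export
sh_n_coef <- function(lmax) {
  stopifnot(length(lmax) == 1L, lmax >= 0, lmax %% 2 == 0)
  as.integer((lmax + 1L) * (lmax + 2L) / 2L)
}

#' Infer the spherical-harmonic order from a coefficient count
#'
#' @param n_coef Number of even-order coefficients.
#' @return The even order `lmax` such that `sh_n_coef(lmax) == n_coef`.
#' @export
sh_order_from_n <- function(n_coef) {
  lmax <- (sqrt(8 * n_coef + 1) - 3) / 2
  lmax <- as.integer(round(lmax))
  if (lmax < 0 || lmax %% 2 != 0 || sh_n_coef(lmax) != n_coef)
    stop("coefficient count ", n_coef,
         " does not correspond to an even spherical-harmonic order")
  lmax
}

# Associated Legendre functions P_l^m(x) for m = 0..l, Condon-Shortley phase
# included (P_1^1(x) = -sqrt(1 - x^2)). Standard stable recurrence:
# diagonal P_m^m, then upward in l.
assoc_legendre <- function(l, m, x) {
  stopifnot(m >= 0, m <= l)
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, 1 - x^2))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- -pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  pll <- pmmp1
  for (ll in (m + 2):l) {
    pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pll
}

#' Real even-order spherical-harmonic basis matrix
#'
#' Evaluates the real, orthonormal, even-order spherical-harmonic basis at a
#' set of unit directions. The convention is the one common in diffusion-MRI
#' software: for each even order l, the `l(l+1)/2 + m + 1`-th column holds,
#' with `N_lm = sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!)` and Condon-Shortley phase
#' inside `P_l^m`:
#' \itemize{
#'   \item `m < 0`:  `sqrt(2) N_l|m| P_l^|m|(cos theta) sin(|m| phi)`
#'   \item `m = 0`:  `N_l0 P_l^0(cos theta)`
#'   \item `m > 0`:  `sqrt(2) N_lm P_l^m(cos theta) cos(m phi)`
#' }
#' so that an amplitude vector is `B %*% coefficients`.
#'
#' @param directions Numeric matrix, n x 3, unit vectors.
#' @param lmax Even maximum order.
#' @return n x `sh_n_coef(lmax)` basis matrix.
#' @export
sh_basis <- function(directions, lmax) {
  directions <- rbind(directions)
  stopifnot(ncol(directions) == 3, lmax %% 2 == 0)
  x <- directions[, 1]; y <- directions[, 2]; z <- directions[, 3]
  phi <- atan2(y, x)
  ct <- pmin(1, pmax(-1, z))
  B <- matrix(0, nrow(directions), sh_n_coef(lmax))
  for (l in seq(0, lmax, by = 2)) {
    base <- l * (l + 1) / 2 + 1  # column of m = 0 is base + 0 shifted below
    for (m in 0:l) {
      nlm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lfactorial(l - m) - lfactorial(l + m)))
      plm <- assoc_legendre(l, m, ct)
      if (m == 0) {
        B[, base] <- nlm * plm
      } else {
        B[, base + m] <- sqrt(2) * nlm * plm * cos(m * phi)
        B[, base - m] <- sqrt(2) * nlm * plm * sin(m * phi)
      }
    }
  }
  B
}

#' Project sampled spherical values onto the even spherical-harmonic basis
#'
#' Least-squares fit of coefficients to amplitude samples; exact (up to
#' numerical precision) when the sampled function is band-limited at `lmax`
#' and the directions over-determine the basis.
#'
#' @param directions n x 3 unit vectors.
#' @param values Amplitudes sampled at `directions`.
#' @param lmax Even order of the fit.
#' @return Coefficient vector of length `sh_n_coef(lmax)`.
#' @export
sh_project <- function(directions, values, lmax) {
  B <- sh_basis(directions, lmax)
  if (nrow(B) < ncol(B))
    stop("need at least ", ncol(B), " directions to fit order ", lmax)
  qr.coef(qr(B), values)
}

# Spherical integral of an SH expansion: only Y_00 = 1/(2 sqrt(pi)) has a
# nonzero integral (2 sqrt(pi)), so the whole-sphere integral is c0 * 2 sqrt(pi).
sh_integral <- function(coefficients) {
  coefficients[1] * 2 * sqrt(pi)
}

# Coefficients of the axially symmetric, nonnegative lobe kernel
# f(d) = amplitude_scale * (d . axis)^(2p) with 2p = lmax; a polynomial of
# degree lmax in d, hence exactly band-limited at order lmax. Its sphere
# integral is amplitude_scale * 4 pi / (lmax + 1).
sh_lobe_kernel <- function(axis, lmax, integral = 1, mesh = NULL) {
  axis <- axis / sqrt(sum(axis^2))
  if (is.null(mesh)) mesh <- sphere_mesh(3L)
  amp_scale <- integral * (lmax + 1) / (4 * pi)
  f <- amp_scale * (mesh$vertices %*% axis)^lmax
  sh_project(mesh$vertices, drop(f), lmax)
}
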