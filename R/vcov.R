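#' Variance-covariance structure across harvests
#'
#' Describes one of the nine parametric forms used for the genetic (`G_L`)
#' and residual (`R_L`) covariance matrices across `L` harvests:
#'
#' | name   | nPAR        | form                                              |
#' |--------|-------------|---------------------------------------------------|
#' | ID     | 1           | `sigma2 * I`                                      |
#' | DIAG   | L           | `diag(sigma2_1..sigma2_L)`                        |
#' | CS     | 2           | `sigma2 * ((1 - rho) I + rho J)`                  |
#' | CSHet  | L + 1       | `sigma_l sigma_m (rho + (1 - rho) 1{l = m})`      |
#' | AR1    | 2           | `sigma2 * rho^|l - m|`                            |
#' | AR1Het | L + 1       | `sigma_l sigma_m rho^|l - m|`                     |
#' | Po     | 2           | `sigma2 * rho^|t_l - t_m|` on coordinates `t`     |
#' | PoHet  | L + 1       | heterogeneous power model                         |
#' | US     | L(L+1)/2    | free positive semi-definite matrix                |
#'
#' For Po/PoHet the harvest coordinates default to `1..L` (with equally
#' spaced coordinates Po coincides with AR1). For `US` the parameters are the
#' lower-triangle (column-major, diagonal included) of the matrix itself.
#'
#' @param name structure name (see table).
#' @param L number of harvests.
#' @param params optional numeric parameter vector (length `n_vcov_par(name,
#'   L)`): variances first, then the correlation for the homogeneous forms;
#'   standard deviations then correlation for the `Het` forms. Leave `NULL`
#'   when the structure is to be estimated.
#' @param times optional harvest coordinates for Po/PoHet.
#' @return object of class `vcov_structure`.
#' @export
vcov_structure <- function(name, L, params = NULL, times = NULL) {
  name <- match.arg(name, c("ID", "DIAG", "CS", "CSHet", "AR1", "AR1Het",
                            "Po", "PoHet", "US"))
  if (!is_count(L)) stopf("L must be a positive integer")
  if (is.null(times)) times <- seq_len(L)
  if (length(times) != L) stopf("times must have length L")
  if (!is.null(params) && length(params) != n_vcov_par(name, L))
    stopf("%s with L = %d requires %d parameters, got %d", name, L,
          n_vcov_par(name, L), length(params))
  structure(list(name = name, L = as.integer(L), params = params,
                 times = as.numeric(times)), class = "vcov_structure")
}

#' Number of parameters of a VCOV structure
#'
#' @param name structure name.
#' @param L number of harvests.
#' @return integer parameter count.
#' @export
n_vcov_par <- function(name, L) {
  switch(name,
         ID = 1L, CS = 2L, AR1 = 2L, Po = 2L,
         DIAG = as.integer(L),
         CSHet = L + 1L, AR1Het = L + 1L, PoHet = L + 1L,
         US = as.integer(L * (L + 1) / 2),
         stopf("unknown structure '%s'", name))
}

#' Realize a VCOV structure as an L x L matrix
#'
#' @param structure a [vcov_structure()] with parameters set.
#' @return symmetric positive semi-definite `L x L` matrix.
#' @export
build_vcov <- function(structure) {
  s <- structure
  if (is.null(s$params)) stopf("structure has no parameters")
  L <- s$L; th <- s$params; t <- s$times
  J <- matrix(1, L, L); I <- diag(L)
  M <- switch(s$name,
    ID = {
      if (th[1] <= 0) stopf("variance must be > 0")
      th[1] * I
    },
    DIAG = {
      if (any(th <= 0)) stopf("variances must be > 0")
      diag(th, L)
    },
    CS = {
      check_cor(th[2], lower = -1 / max(L - 1, 1))
      th[1] * ((1 - th[2]) * I + th[2] * J)
    },
    CSHet = {
      sds <- th[seq_len(L)]; rho <- th[L + 1]
      if (any(sds <= 0)) stopf("standard deviations must be > 0")
      check_cor(rho, lower = -1 / max(L - 1, 1))
      tcrossprod(sds) * (rho + (1 - rho) * I)
    },
    AR1 = {
      check_cor(th[2])
      th[1] * th[2]^abs(outer(seq_len(L), seq_len(L), `-`))
    },
    AR1Het = {
      sds <- th[seq_len(L)]; rho <- th[L + 1]
      if (any(sds <= 0)) stopf("standard deviations must be > 0")
      check_cor(rho)
      tcrossprod(sds) * rho^abs(outer(seq_len(L), seq_len(L), `-`))
    },
    Po = {
      if (th[2] <= 0 || th[2] >= 1) stopf("Po correlation must lie in (0, 1)")
      th[1] * th[2]^abs(outer(t, t, `-`))
    },
    PoHet = {
      sds <- th[seq_len(L)]; rho <- th[L + 1]
      if (any(sds <= 0)) stopf("standard deviations must be > 0")
      if (rho <= 0 || rho >= 1) stopf("Po correlation must lie in (0, 1)")
      tcrossprod(sds) * rho^abs(outer(t, t, `-`))
    },
    US = {
      M <- matrix(0, L, L)
      M[lower.tri(M, diag = TRUE)] <- th
      M <- M + t(M) - diag(diag(M))
      ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev)))
        stopf("US parameters do not form a positive semi-definite matrix")
      M
    })
  dimnames(M) <- list(paste0("h", seq_len(L)), paste0("h", seq_len(L)))
  M
}

check_cor <- function(rho, lower = -1) {
  if (rho <= lower || rho >= 1)
    stopf("correlation must lie in (%.3f, 1)", lower)
  invisible(rho)
}

# ---- internal transforms between unconstrained optimizer space and the
# structure parameter vector -------------------------------------------------

vcov_npar_internal <- function(name, L) n_vcov_par(name, L)

# initial unconstrained parameters given a variance scale
vcov_init <- function(name, L, v0) {
  lv <- log(v0)
  switch(name,
    ID = lv,
    DIAG = rep(lv, L),
    CS = c(lv, 0),
    CSHet = c(rep(lv / 2, L), 0),
    AR1 = c(lv, 0),
    AR1Het = c(rep(lv / 2, L), 0),
    Po = c(lv, 0),
    PoHet = c(rep(lv / 2, L), 0),
    US = c(rep(lv / 2, L), rep(0, L * (L - 1) / 2)))
}

# map unconstrained vector to constrained structure params
vcov_untransform <- function(name, L, u) {
  cs_lower <- -1 / max(L - 1, 1)
  switch(name,
    ID = exp(u),
    DIAG = exp(u),
    CS = c(exp(u[1]), cs_lower + (1 - cs_lower) * plogis(u[2])),
    CSHet = c(exp(u[seq_len(L)]),
              cs_lower + (1 - cs_lower) * plogis(u[L + 1])),
    AR1 = c(exp(u[1]), tanh(u[2])),
    AR1Het = c(exp(u[seq_len(L)]), tanh(u[L + 1])),
    Po = c(exp(u[1]), plogis(u[2])),
    PoHet = c(exp(u[seq_len(L)]), plogis(u[L + 1])),
    US = u)  # log-Cholesky, materialized separately
}

# materialize the matrix from unconstrained parameters (fitting path)
vcov_materialize <- function(name, L, u, times) {
  if (name == "US") {
    C <- matrix(0, L, L)
    C[cbind(seq_len(L), seq_len(L))] <- exp(u[seq_len(L)])
    if (L > 1) C[lower.tri(C)] <- u[-seq_len(L)]
    return(tcrossprod(C))
  }
  build_vcov(vcov_structure(name, L, params = vcov_untransform(name, L, u),
                            times = times))
}

# recover reporting-scale parameters from unconstrained vector
vcov_report_params <- function(name, L, u) {
  if (name == "US") {
    M <- vcov_materialize("US", L, u, seq_len(L))
    return(M[lower.tri(M, diag = TRUE)])
  }
  vcov_untransform(name, L, u)
}
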