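# Interior-point solver for the weighted-slack LP-SVM.
#
# The LP solved is, for l training rows and l' kernel columns:
#
#   min  -r + sum_i c*theta_i * xi_i
#   s.t. y_i (sum_j alpha_j y'_j K_ij + b) >= r - xi_i   (i = 1..l)
#        -1 <= alpha_j <= 1                              (j = 1..l')
#        xi_i >= 0, r >= 0, b free.
#
# Rather than handing a generic dense LP to a simplex code, the Newton
# systems of a Mehrotra predictor-corrector method are reduced analytically:
# the xi block of the normal matrix is diagonal, so each step costs one
# (l'+2)-dimensional Cholesky plus O(l * l'^2) to form it. That keeps the
# full 600-row problem at a few hundred milliseconds and the reduced-column
# problem essentially free.

# Solve the LP-SVM. Hm = Diag(y) K Diag(y'), y in {-1,1}^l, cost_xi = c*theta.
# Returns list(alpha, b, r, xi, objective, status, iterations).
.lpsvm_ipm <- function(Hm, y, cost_xi, tol = 1e-9, max_iter = 200L) {
  l  <- nrow(Hm)
  lp <- ncol(Hm)
  p  <- lp + 1L                       # u = (alpha, b)
  P  <- cbind(Hm, y)                  # margin row i: -P_i u + r - xi_i <= 0

  # objective over x = (u, r, xi)
  c_u  <- numeric(p)
  c_r  <- -1
  c_xi <- cost_xi

  # inequality rows: margin (l), alpha <= 1 (lp), -alpha <= 1 (lp),
  # -r <= 0 (1), -xi <= 0 (l); slack s >= 0, dual z >= 0 per row.
  m <- l + 2L * lp + 1L + l
  h <- c(numeric(l), rep(1, 2L * lp), 0, numeric(l))

  # G x by blocks (avoids materializing G)
  gmul <- function(u, r, xi) {
    Pu <- drop(P %*% u)
    c(-Pu + r - xi, u[seq_len(lp)], -u[seq_len(lp)], -r, -xi)
  }
  # G^T q by blocks -> list(u, r, xi)
  gtmul <- function(q) {
    qm <- q[seq_len(l)]
    qu <- q[l + seq_len(lp)]
    ql <- q[l + lp + seq_len(lp)]
    qr <- q[l + 2L * lp + 1L]
    qx <- q[l + 2L * lp + 1L + seq_len(l)]
    list(u = drop(-crossprod(P, qm)) + c(qu - ql, 0),
         r = sum(qm) - qr,
         xi = -qm - qx)
  }

  u <- numeric(p); r <- 0; xi <- numeric(l)
  s <- rep(1, m);  z <- rep(1, m)
  cnorm <- 1 + max(abs(c(c_u, c_r, c_xi)))
  hnorm <- 1 + max(abs(h))
  status <- "max_iterations"
  it <- 0L

  for (it in seq_len(max_iter)) {
    rp <- gmul(u, r, xi) + s - h                      # primal residual
    gtz <- gtmul(z)
    rd_u  <- c_u  + gtz$u                             # dual residuals
    rd_r  <- c_r  + gtz$r
    rd_xi <- c_xi + gtz$xi
    mu <- sum(s * z) / m

    pinf <- max(abs(rp)) / hnorm
    dinf <- max(abs(c(rd_u, rd_r, rd_xi))) / cnorm
    if (!all(is.finite(c(mu, pinf, dinf)))) {
      status <- "numerical_failure"; break
    }
    if (mu < tol && pinf < tol && dinf < tol) { status <- "optimal"; break }
    if (max(abs(u), r, abs(xi)) > 1e10) { status <- "unbounded"; break }

    w <- z / s
    w_m <- w[seq_len(l)]
    w_up <- w[l + seq_len(lp)]
    w_lo <- w[l + lp + seq_len(lp)]
    w_r <- w[l + 2L * lp + 1L]
    w_x <- w[l + 2L * lp + 1L + seq_len(l)]

    D <- w_m + w_x
    wt <- w_m * w_x / D                               # xi block eliminated
    wmD <- w_m / D

    A_uu <- crossprod(P * sqrt(wt)) + diag(c(w_up + w_lo, 0), p)
    A_ur <- drop(-crossprod(P, wt))
    A_rr <- sum(wt) + w_r
    M <- rbind(cbind(A_uu, A_ur), c(A_ur, A_rr))
    # tiny static regularization, escalated only if the factorization fails
    delta <- 1e-12 * (1 + mean(diag(M)) / nrow(M))
    R <- NULL
    for (try in 1:6) {
      R <- tryCatch(chol(M + diag(delta, nrow(M))), error = function(e) NULL)
      if (!is.null(R)) break
      delta <- delta * 1e3
    }
    if (is.null(R)) { status <- "factorization_failed"; break }

    # one Newton solve for a given complementarity target rc (length m):
    # direction for (u,r,xi), then ds, dz.
    newton <- function(rc) {
      q <- (rc / s) + w * rp                          # S^{-1} rc + W rp
      gq <- gtmul(q)
      g_u <- -rd_u - gq$u
      g_r <- -rd_r - gq$r
      g_x <- -rd_xi - gq$xi
      gt_u <- g_u - drop(crossprod(P, wmD * g_x))
      gt_r <- g_r + sum(wmD * g_x)
      sol <- backsolve(R, forwardsolve(t(R), c(gt_u, gt_r)))
      du <- sol[seq_len(p)]; dr <- sol[p + 1L]
      # xi block: w_m*(P_i du) - w_m dr + D dxi = g_x
      dxi <- (g_x - w_m * drop(P %*% du) + w_m * dr) / D
      ds <- -rp - gmul(du, dr, dxi)
      dz <- (rc - z * ds) / s
      list(du = du, dr = dr, dxi = dxi, ds = ds, dz = dz)
    }

    step_len <- function(v, dv) {
      neg <- dv < 0
      if (!any(neg)) 1 else min(1, min(-v[neg] / dv[neg]))
    }

    # predictor
    aff <- newton(-s * z)
    if (!all(is.finite(c(aff$du, aff$dr, aff$dxi, aff$ds, aff$dz)))) {
      status <- "numerical_failure"; break
    }
    ap <- step_len(s, aff$ds)
    ad <- step_len(z, aff$dz)
    mu_aff <- sum((s + ap * aff$ds) * (z + ad * aff$dz)) / m
    sigma <- min(1, max(1e-8, (mu_aff / mu)^3))

    # corrector
    dir <- newton(-s * z - aff$ds * aff$dz + sigma * mu)
    if (!all(is.finite(c(dir$du, dir$dr, dir$dxi, dir$ds, dir$dz)))) {
      status <- "numerical_failure"; break
    }
    ap <- 0.9995 * step_len(s, dir$ds)
    ad <- 0.9995 * step_len(z, dir$dz)

    u  <- u  + ap * dir$du
    r  <- r  + ap * dir$dr
    xi <- xi + ap * dir$dxi
    s  <- s  + ap * dir$ds
    z  <- z  + ad * dir$dz
  }

  if (status == "unbounded")
    stop("LP-SVM solve failed with status: unbounded")
  if (status != "optimal") {
    # late-stage numerical trouble: accept the iterate if the duality gap
    # is already small, otherwise fail loudly
    if (is.finite(mu) && mu < 1e-6) status <- "near_optimal"
    else stop("LP-SVM solver did not converge (status: ", status,
              ", mu = ", format(mu), ")")
  }

  # polish onto the feasible set: clamp the bounded variables, then take
  # the minimal feasible slacks for (alpha, b, r) held fixed.
  alpha <- pmin(1, pmax(-1, u[seq_len(lp)]))
  b <- u[p]
  r <- max(r, 0)
  margin <- drop(P %*% c(alpha, b))                   # y_i * f(x_i)
  xi <- pmax(0, r - margin)
  list(alpha = alpha, b = b, r = r, xi = xi,
       objective = -r + sum(cost_xi * xi),
       status = status, iterations = it)
}
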