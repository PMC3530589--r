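# Dense bounded-variable primal simplex, two phases.
#
# Solves   max/min  c'x   s.t.  A x = b,  lb <= x <= ub.
#
# This is the LP engine behind every flux-balance computation in the
# package. It is written for the problem sizes this package targets
# (core-scale networks, up to a few hundred reactions): the basis is
# refactorized by dense solve() at every iteration, which is numerically
# robust and entirely adequate at that scale. Nonbasic variables sit at a
# finite bound (the +/-1000 "unbounded" convention of COBRA-style models is
# kept finite here; true infinities are clamped to +/-1e6), so phase 2 can
# never be unbounded. Entering variables are chosen by largest reduced cost
# (Dantzig) with a switch to Bland's rule after a fixed number of
# iterations, which guarantees termination on degenerate problems.

LP_BIG <- 1e6

lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9,
                     max_iter = NULL) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  LB <- pmax(lb, -LP_BIG)
  UB <- pmin(ub, LP_BIG)
  LB <- pmin(LB, UB) # guard against lb slightly above a clamped ub

  nart <- m
  N <- n + nart
  # start every structural variable at its bound of smaller magnitude
  varstat <- ifelse(abs(LB) <= abs(UB), 1L, 2L) # 1 = at lower, 2 = at upper
  x <- ifelse(varstat == 1L, LB, UB)
  r <- b - as.vector(A %*% x)
  art_sign <- ifelse(r >= 0, 1, -1)
  Af <- cbind(A, diag(art_sign, nrow = m))
  LBf <- c(LB, rep(0, nart))
  UBf <- c(UB, rep(Inf, nart))
  varstat <- c(varstat, rep(0L, nart)) # artificials start basic
  basis <- n + seq_len(nart)
  xf <- c(x, abs(r))

  if (is.null(max_iter)) max_iter <- max(200L, 60L * N)

  run_phase <- function(cvec, varstat, basis, xf, LBf, UBf) {
    dtol <- tol * (1 + max(abs(cvec)))
    piveps <- 1e-10
    bland_after <- 4L * N
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        return(list(status = "maxit", varstat = varstat, basis = basis, xf = xf))
      }
      Bmat <- Af[, basis, drop = FALSE]
      Binv <- tryCatch(solve(Bmat), error = function(e) NULL)
      if (is.null(Binv)) {
        return(list(status = "numerical", varstat = varstat, basis = basis, xf = xf))
      }
      nonbasic <- which(varstat != 0L)
      xN <- ifelse(varstat[nonbasic] == 1L, LBf[nonbasic], UBf[nonbasic])
      xf[nonbasic] <- xN
      rhs <- b - as.vector(Af[, nonbasic, drop = FALSE] %*% xN)
      xB <- as.vector(Binv %*% rhs)
      xf[basis] <- xB

      y <- as.vector(crossprod(Binv, cvec[basis]))
      d <- cvec[nonbasic] - as.vector(crossprod(Af[, nonbasic, drop = FALSE], y))
      movable <- (UBf[nonbasic] - LBf[nonbasic]) > piveps
      improving <- movable &
        ((varstat[nonbasic] == 1L & d > dtol) | (varstat[nonbasic] == 2L & d < -dtol))
      if (!any(improving)) {
        return(list(status = "optimal", varstat = varstat, basis = basis, xf = xf))
      }
      cand <- nonbasic[improving]
      e <- if (iter > bland_after) min(cand) else cand[which.max(abs(d[improving]))]
      tdir <- if (varstat[e] == 1L) 1 else -1
      w <- as.vector(Binv %*% Af[, e])

      # ratio test: xB moves by -tdir * delta * w
      delta <- UBf[e] - LBf[e]
      leave_pos <- NA_integer_
      leave_bound <- NA_integer_
      tw <- tdir * w
      for (i in seq_len(m)) {
        if (tw[i] > piveps) {
          lim <- (xB[i] - LBf[basis[i]]) / tw[i]
          if (lim < delta - 1e-12) {
            delta <- lim
            leave_pos <- i
            leave_bound <- 1L
          }
        } else if (tw[i] < -piveps) {
          lim <- (xB[i] - UBf[basis[i]]) / tw[i]
          if (lim < delta - 1e-12) {
            delta <- lim
            leave_pos <- i
            leave_bound <- 2L
          }
        }
      }
      delta <- max(delta, 0)
      if (is.infinite(delta)) {
        return(list(status = "unbounded", varstat = varstat, basis = basis, xf = xf))
      }
      if (is.na(leave_pos)) {
        # entering variable travels its full range: bound flip
        varstat[e] <- if (varstat[e] == 1L) 2L else 1L
      } else {
        leaving <- basis[leave_pos]
        varstat[leaving] <- leave_bound
        varstat[e] <- 0L
        basis[leave_pos] <- e
        xf[e] <- (if (tdir > 0) LBf[e] else UBf[e]) + tdir * delta
      }
    }
  }

  # phase 1: drive the artificials to zero
  c1 <- c(rep(0, n), rep(-1, nart))
  ph1 <- run_phase(c1, varstat, basis, xf, LBf, UBf)
  if (ph1$status %in% c("maxit", "numerical")) {
    return(list(status = ph1$status, x = rep(NA_real_, n), objective = NA_real_))
  }
  art_sum <- sum(ph1$xf[n + seq_len(nart)])
  scale1 <- 1 + max(abs(b), abs(LB[is.finite(LB)]), abs(UB[is.finite(UB)]))
  if (art_sum > 1e-7 * scale1) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }

  # phase 2: artificials pinned to zero
  UBf[n + seq_len(nart)] <- 0
  c2 <- c(if (maximize) obj else -obj, rep(0, nart))
  ph2 <- run_phase(c2, ph1$varstat, ph1$basis, ph1$xf, LBf, UBf)
  if (ph2$status %in% c("maxit", "numerical")) {
    return(list(status = ph2$status, x = rep(NA_real_, n), objective = NA_real_))
  }
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))
  }
  xsol <- ph2$xf[seq_len(n)]
  # snap residual roundoff onto the box
  xsol <- pmin(pmax(xsol, LB), UB)
  list(
    status = "optimal",
    x = xsol,
    objective = sum(obj * xsol)
  )
}
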