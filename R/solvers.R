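# Thin deterministic wrappers around pracma's LP / QP solvers.
#
# pracma::linprog assumes x >= 0 and its lb/ub code path is unreliable, so we
# shift variables by their (finite) lower bounds and encode upper bounds as
# inequality rows. Problems here are tiny (tens of variables), so the dense
# simplex / active-set methods are adequate.

BIGBND <- 1e6

lp_box <- function(obj, A = NULL, b = NULL, Aeq = NULL, beq = NULL,
                   lb = NULL, ub = NULL, maximize = FALSE) {
  n <- length(obj)
  if (is.null(lb)) lb <- rep(0, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  lb[!is.finite(lb)] <- -BIGBND
  ubf <- pmin(ub, BIGBND)
  # substitute x = lb + y, y >= 0
  A2 <- if (!is.null(A)) as.matrix(A) else matrix(0, 0, n)
  b2 <- if (!is.null(b)) as.numeric(b) - as.numeric(A2 %*% lb) else numeric(0)
  # upper bounds as rows y_i <= ub_i - lb_i
  ib <- which(is.finite(ubf - lb) & (ubf - lb) < BIGBND * 2)
  if (length(ib)) {
    Ub <- matrix(0, length(ib), n)
    Ub[cbind(seq_along(ib), ib)] <- 1
    A2 <- rbind(A2, Ub)
    b2 <- c(b2, ubf[ib] - lb[ib])
  }
  Aeq2 <- if (!is.null(Aeq)) as.matrix(Aeq) else NULL
  beq2 <- if (!is.null(Aeq)) as.numeric(beq) - as.numeric(Aeq2 %*% lb) else NULL
  res <- tryCatch(
    pracma::linprog(cc = as.numeric(obj),
                    A = if (nrow(A2)) A2 else NULL,
                    b = if (nrow(A2)) b2 else NULL,
                    Aeq = Aeq2, beq = beq2,
                    maxiter = max(200L, 20L * n), maximize = maximize),
    error = function(e) NULL
  )
  if (is.null(res) || is.null(res$x) || anyNA(res$x)) {
    return(list(ok = FALSE, x = rep(NA_real_, n), value = NA_real_))
  }
  x <- lb + res$x
  list(ok = isTRUE(res$errno == 1) || grepl("converged", res$message %||% ""),
       x = x, value = sum(obj * x))
}

qp_box <- function(H, f, A = NULL, b = NULL, Aeq = NULL, beq = NULL,
                   lb = NULL, ub = NULL) {
  n <- length(f)
  Aineq <- if (!is.null(A)) as.matrix(A) else matrix(0, 0, n)
  bineq <- if (!is.null(b)) as.numeric(b) else numeric(0)
  if (!is.null(lb)) {
    ii <- which(is.finite(lb))
    if (length(ii)) {
      Lb <- matrix(0, length(ii), n); Lb[cbind(seq_along(ii), ii)] <- -1
      Aineq <- rbind(Aineq, Lb); bineq <- c(bineq, -lb[ii])
    }
  }
  if (!is.null(ub)) {
    ii <- which(is.finite(ub))
    if (length(ii)) {
      Ub <- matrix(0, length(ii), n); Ub[cbind(seq_along(ii), ii)] <- 1
      Aineq <- rbind(Aineq, Ub); bineq <- c(bineq, ub[ii])
    }
  }
  res <- pracma::quadprog(C = as.matrix(H), d = as.numeric(f),
                          A = if (nrow(Aineq)) Aineq else NULL,
                          b = if (nrow(Aineq)) bineq else NULL,
                          Aeq = if (!is.null(Aeq)) as.matrix(Aeq) else NULL,
                          beq = if (!is.null(Aeq)) as.numeric(beq) else NULL)
  if (is.null(res$xmin) || anyNA(res$xmin)) stop("QP solver failed")
  as.numeric(res$xmin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
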