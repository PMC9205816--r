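#' @export
print.megblup <- function(x, ...) {
  cat(sprintf("Multi-environment %s mixed model (%s engine)\n",
              if ((attr(x$K, "kind") %||% "genomic") == "genomic") "GBLUP"
              else "PBLUP", x$engine))
  cat(sprintf("  %d plots, %d environments, %d lines in kinship\n",
              x$design$n, length(x$design$env_levels), nrow(x$K)))
  cat(sprintf("  REML log-likelihood: %.4f (%s)\n", x$loglik,
              if (x$convergence$converged) "converged" else "NOT converged"))
  if (!is.null(x$varcomp$Go)) {
    cat("  plot-level heritability per environment:\n")
    h2 <- plot_heritability(x$varcomp)
    cat("   ", paste(sprintf("%s=%.2f", names(h2), h2), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.megblup <- function(object, ...) {
  out <- list(varcomp = object$varcomp,
              h2 = if (!is.null(object$varcomp$Go))
                plot_heritability(object$varcomp) else NULL,
              gcor = if (!is.null(object$varcomp$Go) &&
                         ncol(object$varcomp$Go) > 1)
                genetic_correlations(object$varcomp$Go) else NULL,
              loglik = object$loglik,
              convergence = object$convergence,
              engine = object$engine,
              n = object$design$n)
  class(out) <- "summary.megblup"
  out
}

#' @export
print.summary.megblup <- function(x, ...) {
  cat(sprintf("REML fit (%s engine), %d plots, log-likelihood %.4f\n",
              x$engine, x$n, x$loglik))
  cat("\nVariance components:\n")
  if (length(x$varcomp$sigma2)) {
    for (nm in names(x$varcomp$sigma2)) {
      cat(sprintf("  %-12s %10.5f\n", nm, x$varcomp$sigma2[[nm]]))
    }
  }
  cat("  residual variance:\n")
  print(round(x$varcomp$resid_var, 5))
  if (!is.null(x$varcomp$Go)) {
    cat("\nGenetic covariance between environments (Go = LL' + Psi):\n")
    print(round(x$varcomp$Go, 4))
    if (!is.null(x$gcor)) {
      cat("\nGenetic correlations:\n")
      print(round(x$gcor, 3))
    }
    cat("\nPlot-level heritability:\n")
    print(round(x$h2, 3))
  }
  if (!is.null(x$varcomp$spatial_rho)) {
    cat("\nSpatial AR1 correlations (col, row):\n")
    print(round(x$varcomp$spatial_rho, 3))
  }
  if (!x$convergence$converged) {
    cat("\nWARNING: REML iterations did not converge\n")
  }
  invisible(x)
}

#' @export
coef.megblup <- function(object, ...) object$fixed

#' @export
fitted.megblup <- function(object, ...) object$fitted

#' @export
residuals.megblup <- function(object, ...) object$residuals

#' @export
logLik.megblup <- function(object, ...) {
  structure(object$loglik, df = NA_integer_,
            nobs = object$design$n, class = "logLik")
}

#' Predicted genetic effects (GBLUP/PBLUP) for chosen lines and environments
#'
#' Returns the empirical-BLUP genetic effect of each requested (line,
#' environment) cell — including cells never phenotyped, which are predicted
#' through the kinship and between-environment covariance.  An unphenotyped
#' line with no kinship to any phenotyped line has prediction exactly zero.
#'
#' @param object a [megblup()] fit.
#' @param lines line ids (default: all lines of the kinship matrix).
#' @param envs environment labels (default: all fitted environments).
#' @param ... unused.
#' @return lines x environments numeric matrix.
#' @export
predict.megblup <- function(object, lines = NULL, envs = NULL, ...) {
  G <- object$gblups
  if (is.null(G)) stop("fit has no genetic term")
  lines <- lines %||% rownames(G)
  envs <- envs %||% colnames(G)
  bad <- setdiff(lines, rownames(G))
  if (length(bad)) {
    stop("line(s) not in the kinship used at fit time: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad_e <- setdiff(envs, colnames(G))
  if (length(bad_e)) stop("unknown environment(s): ",
                          paste(bad_e, collapse = ", "))
  G[lines, envs, drop = FALSE]
}

#' @rdname predict.megblup
#' @param fit a [megblup()] fit.
#' @export
predict_gblup <- function(fit, lines = NULL, envs = NULL) {
  predict(fit, lines = lines, envs = envs)
}

#' @export
plot.megblup <- function(x, which = c("correlations", "heritability"), ...) {
  which <- match.arg(which)
  if (is.null(x$varcomp$Go)) stop("fit has no genetic term")
  if (which == "correlations") {
    R <- genetic_correlations(x$varcomp$Go)
    k <- ncol(R)
    graphics::image(seq_len(k), seq_len(k), t(R[k:1, , drop = FALSE]),
                    zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                    col = grDevices::hcl.colors(41, "Blue-Red 3", rev = TRUE),
                    main = "Genetic correlations between environments")
    graphics::axis(1, seq_len(k), colnames(R), las = 2, cex.axis = 0.8)
    graphics::axis(2, seq_len(k), rev(rownames(R)), las = 2, cex.axis = 0.8)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      graphics::text(j, k - i + 1, sprintf("%.2f", R[i, j]), cex = 0.7)
    }
  } else {
    h2 <- plot_heritability(x$varcomp)
    graphics::barplot(h2, ylim = c(0, 1), ylab = "plot-level heritability",
                      las = 2)
  }
  invisible(x)
}

#' Simulate phenotype vectors from a fitted model
#'
#' Draws new phenotype vectors at the plots of the fitted design from the
#' estimated variance components (fixed effects at their estimates, random
#' effects and residuals redrawn).
#'
#' @param object a [megblup()] fit.
#' @param nsim number of simulated vectors.
#' @param seed integer seed.
#' @param ... unused.
#' @return data frame with one column per simulation.
#' @export
simulate.megblup <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) local_rng(seed)
  design <- object$design
  vc <- object$varcomp
  n <- design$n
  k <- length(design$env_levels)
  s2e <- if (length(vc$resid_var) == k) vc$resid_var else
    rep(vc$resid_var[1], k)
  out <- matrix(0, n, nsim)
  mu <- if (object$engine == "balanced") {
    # balanced fits store per-environment means and a replicate contrast
    reps <- sort(unique(design$pheno$rep))
    as.numeric(object$fixed[paste0("mean:", design$envg)]) +
      ifelse(design$pheno$rep == reps[1], -0.5, 0.5) *
        object$fixed[["rep_contrast"]]
  } else {
    as.numeric(design$X %*% object$fixed[colnames(design$X)])
  }
  UK <- chol(as.matrix(object$K))
  for (sim in seq_len(nsim)) {
    y <- mu
    for (nm in names(design$terms)) {
      tm <- design$terms[[nm]]
      if (tm$type == "iid") {
        u <- stats::rnorm(ncol(tm$Z), 0, sqrt(vc$sigma2[[nm]]))
      } else {
        Zn <- matrix(stats::rnorm(tm$N * tm$k), tm$N, tm$k)
        u <- as.numeric(crossprod(UK, Zn) %*% chol_psd(vc$Go))
      }
      y <- y + as.numeric(tm$Z %*% u)
    }
    for (i in seq_len(k)) {
      idx <- design$env_idx[[i]]
      if (!is.null(vc$spatial_rho) &&
          any(vc$spatial_rho[i, ] != 0)) {
        ph <- design$pheno[idx, ]
        Cc <- outer(ph$col, ph$col, function(a, b)
          vc$spatial_rho[i, 1]^abs(a - b)) *
          outer(ph$row, ph$row, function(a, b)
            vc$spatial_rho[i, 2]^abs(a - b))
        y[idx] <- y[idx] + sqrt(s2e[i]) *
          as.numeric(crossprod(chol(Cc), stats::rnorm(length(idx))))
      } else {
        y[idx] <- y[idx] + stats::rnorm(length(idx), 0, sqrt(s2e[i]))
      }
    }
    out[, sim] <- y
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
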