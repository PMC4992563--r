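# print / summary / plot methods for the package's classes (base graphics,
# in the style of classic modelling packages).

#' @export
print.evofba_model <- function(x, ...) {
  cat("Stoichiometric model:", x$model_id, "\n")
  cat("  reactions:  ", length(x$reactions), "\n")
  cat("  metabolites:", length(x$metabolites), "\n")
  cat("  exchanges:  ", length(x$exchange_reactions),
      sprintf("(%d mutable, %d unlimited)\n", length(x$mutable_exchanges),
              length(x$unlimited_exchanges)))
  cat("  biomass:    ", x$biomass_reaction, "\n")
  invisible(x)
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("FBA solution:", x$status, "\n")
  cat("  growth rate:", format(x$growth_rate, digits = 6), "1/h\n")
  cat("  total |flux|:", format(x$total_flux, digits = 6), "\n")
  up <- x$exchange_fluxes[x$exchange_fluxes > 1e-9]
  sec <- x$exchange_fluxes[x$exchange_fluxes < -1e-9]
  if (length(up)) {
    cat("  uptake:  ")
    cat(paste0(names(up), " ", format(up, digits = 4)), sep = ", ")
    cat("\n")
  }
  if (length(sec)) {
    cat("  secretion:")
    cat(paste0(" ", names(sec), " ", format(-sec, digits = 4)), sep = ",")
    cat("\n")
  }
  invisible(x)
}

#' @export
print.evofba_genotype <- function(x, ...) {
  cat("Genotype", x$id,
      if (!is.na(x$parent_id)) paste0("(parent ", x$parent_id, ")") else "(ancestor)",
      "\n")
  v <- x$v_max[x$v_max > 1e-6]
  cat("  v_max (mmol/gDW/h):",
      paste0(names(v), " = ", format(v, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.evofba_config <- function(x, ...) {
  cat("evoFBA configuration\n")
  cat(sprintf("  model %s | %d cycles x %g h, dt %g min | V = %g l\n",
              if (is.character(x$model)) x$model else "(object)",
              x$cycles, x$cycle_hours, x$dt_min, x$volume))
  cat(sprintf("  dilution %g | C_total %g | K_m %g | mutation rate %g, step %g\n",
              x$dilution_fraction, x$C_total, x$K_m, x$mutation_rate,
              x$mutation_step))
  cat(sprintf("  growth update: %s | seed %d\n", x$growth_update, x$seed))
  invisible(x)
}

#' @export
print.evofba_experiment <- function(x, ...) {
  cat("evoFBA experiment:", x$model_id, "\n")
  n_cyc <- length(x$counts_post)
  cat(sprintf("  %d cycles, %d genotypes created, %d mutation events\n",
              n_cyc, length(x$genotypes), length(x$events)))
  fin <- x$final$biomass
  cat(sprintf("  final population: %d genotype(s), %.3g cells\n",
              length(fin), sum(floor(fin / x$config$cell_mass))))
  invisible(x)
}

#' @export
summary.evofba_experiment <- function(object, ...) {
  surv <- survivors(object, 1L)
  fin <- object$final$biomass
  model <- resolve_model(object$config$model)
  glc <- resolve_exchange(model, "glucose")
  ace <- resolve_exchange(model, "acetate")
  vm <- t(vapply(names(fin), function(id)
    object$genotypes[[id]]$v_max[c(glc, ace)], numeric(2)))
  colnames(vm) <- c("v_max_glucose", "v_max_acetate")
  out <- list(
    cycles = length(object$counts_post),
    genotypes_created = length(object$genotypes),
    survived_a_transfer = length(surv),
    final = data.frame(genotype_id = as.integer(names(fin)),
                       cells = as.numeric(floor(fin / object$config$cell_mass)),
                       vm, row.names = NULL))
  class(out) <- "summary.evofba_experiment"
  out
}

#' @export
print.summary.evofba_experiment <- function(x, ...) {
  cat("evoFBA experiment summary\n")
  cat(sprintf("  cycles run:            %d\n", x$cycles))
  cat(sprintf("  genotypes created:     %d\n", x$genotypes_created))
  cat(sprintf("  survived >=1 transfer: %d\n", x$survived_a_transfer))
  cat("  final population:\n")
  print(x$final, row.names = FALSE)
  invisible(x)
}

#' Plot a cycle trajectory
#'
#' Two stacked panels: substrate concentrations (glucose and acetate
#' highlighted) and per-genotype biomass over the day.
#'
#' @param x a `cycle_trajectory`.
#' @param ... passed to `matplot`.
#' @export
plot.cycle_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  al <- x$aliases
  keysub <- intersect(c(al[["glucose"]], al[["acetate"]]), colnames(x$conc))
  graphics::matplot(x$time, x$conc[, keysub, drop = FALSE], type = "l",
                    lty = 1, col = c("dodgerblue3", "firebrick3"),
                    xlab = "time (min)", ylab = "conc (mmol/l)", ...)
  graphics::legend("topright", legend = c("glucose", "acetate"), lty = 1,
                   col = c("dodgerblue3", "firebrick3"), bty = "n")
  graphics::matplot(x$time, x$biomass, type = "l", lty = 1,
                    xlab = "time (min)", ylab = "biomass (gDW)")
  invisible(x)
}

#' Plot an experiment's survivor trajectories
#'
#' Post-dilution cell counts per genotype across cycles on a log scale.
#'
#' @param x an `evofba_experiment`.
#' @param ... passed to `plot`.
#' @export
plot.evofba_experiment <- function(x, ...) {
  tab <- survivors_table(x, "post")
  if (is.null(tab)) { warning("no survivor data"); return(invisible(x)) }
  ids <- unique(tab$genotype_id)
  graphics::plot(NULL, xlim = range(tab$cycle), ylim = c(1, max(tab$cells)),
                 log = "y", xlab = "cycle", ylab = "cells (post-dilution)",
                 ...)
  for (i in seq_along(ids)) {
    d <- tab[tab$genotype_id == ids[[i]], ]
    graphics::lines(d$cycle, pmax(d$cells, 1), col = i)
  }
  invisible(x)
}
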