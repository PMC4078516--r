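# Five-torsion grid conformational search: exhaustive enumeration of torsion
# combinations on a template (default 60-degree steps, phases 0 inclusive to
# 360 exclusive), local relaxation restricted to the driven torsions under a
# pluggable energy model (coordinate descent; bond lengths and angles stay
# fixed -- full Cartesian relaxation belongs to the quantum-chemistry stage,
# which is out of scope), circular deduplication and A#/B# ranking.

#' Grid-search configuration
#'
#' @param step grid step in degrees; 360 must be divisible by it (default
#'   60, i.e. six phases per torsion).
#' @param torsions which chain torsions to drive (default all five).
#' @param tol_energy convergence tolerance on the energy, kcal/mol.
#' @param tol_angle convergence tolerance on torsion moves, degrees.
#' @param dedup_tol per-torsion circular merge tolerance, degrees (default
#'   20, half the smallest spacing between neighbouring reference minima).
#' @param seed integer seed for any stochastic restart (the default
#'   coordinate descent is deterministic; the seed is recorded for
#'   reproducibility of the output).
#' @param max_sweeps cap on coordinate-descent sweeps per start.
#' @return a `search_config` list.
#' @export
search_config <- function(step = 60, torsions = names(TORSION_DEFS),
                          tol_energy = 1e-6, tol_angle = 0.01,
                          dedup_tol = 20, seed = 1L, max_sweeps = 60L) {
  if (360 %% step != 0) {
    stop("configuration error: 360 must be divisible by step", call. = FALSE)
  }
  torsions <- match.arg(torsions, names(TORSION_DEFS), several.ok = TRUE)
  stopifnot(tol_energy > 0, tol_angle > 0, dedup_tol > 0)
  structure(list(step = step, torsions = torsions, tol_energy = tol_energy,
                 tol_angle = tol_angle, dedup_tol = dedup_tol,
                 seed = as.integer(seed), max_sweeps = as.integer(max_sweeps)),
            class = "search_config")
}

#' Enumerate grid start points
#'
#' Cartesian product of phases `0, step, ..., 360 - step` per driven
#' torsion, normalized to `(-180, 180]`. With the default configuration this
#' is 6^5 = 7776 starts.
#'
#' @param config a [search_config()].
#' @return data.frame, one column per driven torsion, one row per start.
#' @export
grid_starts <- function(config = search_config()) {
  phases <- wrap_angle(seq(0, 360 - config$step, by = config$step))
  g <- do.call(expand.grid, stats::setNames(
    rep(list(phases), length(config$torsions)), config$torsions))
  g[] <- lapply(g, as.numeric)
  g
}

# Fast torsion driver over a plain coordinate matrix: precomputes, per
# driven torsion, the four defining atom indices and the set of atoms on the
# rotating (distal) side of the axis. Equivalent to repeated set_torsion()
# calls but without per-evaluation data.frame overhead.
torsion_driver <- function(template, torsions) {
  lab <- template$atoms$label
  adj <- bond_adjacency(template)
  X0 <- cbind(template$atoms$x, template$atoms$y, template$atoms$z)
  info <- lapply(torsions, function(t) {
    d <- TORSION_DEFS[[t]]
    idx <- match(d, lab)
    if (anyNA(idx)) stop("template lacks atoms for ", t, call. = FALSE)
    side <- reachable_atoms(adj, idx[3L], drop_edge = idx[2:3])
    if (idx[2L] %in% side) {
      stop("topology error: axis of ", t, " lies on a ring", call. = FALSE)
    }
    list(idx = idx, move = setdiff(side, idx[3L]))
  })
  names(info) <- torsions
  conf0 <- template
  list(
    X0 = X0,
    set_one = function(X, t, value) {
      ii <- info[[t]]$idx
      cur <- dihedral_angle(X[ii[1L], ], X[ii[2L], ], X[ii[3L], ], X[ii[4L], ])
      delta <- wrap_angle(value - cur)
      if (abs(delta) < 1e-12) return(X)
      mv <- info[[t]]$move
      X[mv, ] <- rotate_points(X[mv, , drop = FALSE], X[ii[3L], ],
                               X[ii[3L], ] - X[ii[2L], ], delta)
      X
    },
    set_many = function(X, phi) {
      for (t in names(phi)) {
        ii <- info[[t]]$idx
        cur <- dihedral_angle(X[ii[1L], ], X[ii[2L], ], X[ii[3L], ],
                              X[ii[4L], ])
        delta <- wrap_angle(phi[[t]] - cur)
        if (abs(delta) >= 1e-12) {
          mv <- info[[t]]$move
          X[mv, ] <- rotate_points(X[mv, , drop = FALSE], X[ii[3L], ],
                                   X[ii[3L], ] - X[ii[2L], ], delta)
        }
      }
      X
    },
    make_conf = function(X) {
      conf0$atoms$x <- X[, 1L]
      conf0$atoms$y <- X[, 2L]
      conf0$atoms$z <- X[, 3L]
      conf0
    })
}

# one-dimensional line search on a circle: coarse scan every `coarse`
# degrees, then golden-section refinement of the best bracket
line_search_torsion <- function(eval_at, current, coarse = 15) {
  cand <- wrap_angle(seq(0, 360 - coarse, by = coarse) + current)
  ev <- vapply(cand, eval_at, numeric(1L))
  best <- which.min(ev)
  lo <- cand[best] - coarse
  hi <- cand[best] + coarse
  opt <- stats::optimize(function(x) eval_at(wrap_angle(x)),
                         lower = lo, upper = hi, tol = 1e-4)
  if (opt$objective <= ev[best]) {
    list(value = wrap_angle(opt$minimum), energy = opt$objective)
  } else {
    list(value = cand[best], energy = ev[best])
  }
}

#' Exhaustive torsion-grid conformational search
#'
#' Enumerates all grid starts, relaxes each by cyclic coordinate descent
#' over the driven torsions under `model`, and reports one local minimum per
#' convergent start with its energy relative to the global minimum found.
#' Starts where the model is non-finite are skipped with a message.
#' Deterministic given the configuration.
#'
#' @param template a [conformation] passing [validate_topology()].
#' @param model an energy model: function mapping a conformation to a scalar
#'   energy in kcal/mol (see [toy_energy_model()]).
#' @param config a [search_config()].
#' @return an object of class `grid_search_result`: list with `minima` (a
#'   data.frame of final torsions, `energy` relative to the best minimum,
#'   `energy_abs`, and the start phases `start_*`), `conformations` (list of
#'   relaxed conformations) and `config`.
#' @export
grid_search <- function(template, model, config = search_config()) {
  viol <- validate_topology(template)
  if (length(viol)) {
    stop("template fails topology validation: ", viol[1L], call. = FALSE)
  }
  starts <- grid_starts(config)
  tors <- config$torsions
  drv <- torsion_driver(template, tors)
  res <- vector("list", nrow(starts))
  confs <- vector("list", nrow(starts))
  skipped <- 0L
  for (s in seq_len(nrow(starts))) {
    phi <- stats::setNames(as.numeric(starts[s, ]), tors)
    X <- drv$set_many(drv$X0, phi)
    e <- model(drv$make_conf(X))
    if (!is.finite(e)) {
      if (is.nan(e)) {
        stop("model error: energy is NaN at start ", s, call. = FALSE)
      }
      skipped <- skipped + 1L
      next
    }
    for (sweep in seq_len(config$max_sweeps)) {
      e_prev <- e
      moved <- 0
      for (t in tors) {
        eval_at <- function(v) {
          ee <- model(drv$make_conf(drv$set_one(X, t, v)))
          if (is.finite(ee)) ee else 1e6
        }
        ls <- line_search_torsion(eval_at, phi[[t]])
        if (ls$energy < e - 1e-12) {
          moved <- max(moved, circular_diff(ls$value, phi[[t]]))
          phi[[t]] <- ls$value
          X <- drv$set_one(X, t, ls$value)
          e <- ls$energy
        }
      }
      if (e_prev - e < config$tol_energy && moved < config$tol_angle) break
    }
    row <- as.list(phi)
    names(row) <- tors
    row$energy_abs <- e
    for (t in tors) row[[paste0("start_", t)]] <- starts[s, t]
    res[[s]] <- as.data.frame(row)
    confs[[s]] <- drv$make_conf(X)
  }
  keep <- !vapply(res, is.null, logical(1L))
  if (!any(keep)) {
    stop("empty-result error: no convergent start (", skipped,
         " skipped as non-finite)", call. = FALSE)
  }
  minima <- do.call(rbind, res[keep])
  minima$energy <- minima$energy_abs - min(minima$energy_abs)
  rownames(minima) <- NULL
  structure(list(minima = minima, conformations = confs[keep],
                 config = config, skipped = skipped),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> %d minima from %d starts (step %g deg, torsions %s)\n",
              nrow(x$minima), nrow(x$minima) + x$skipped, x$config$step,
              paste(x$config$torsions, collapse = ",")))
  invisible(x)
}

#' Deduplicate grid-search minima and rank them as A1..An / B1..Bm
#'
#' Minima whose driven torsions all agree within the circular
#' `dedup_tol` are merged, keeping the lowest-energy representative.
#' Survivors are split by the sign of phi1 (A: negative/anti, B:
#' positive/syn) and numbered by ascending energy within each class;
#' records with phi1 exactly 0 go to an unclassified `U` bucket with a
#' warning. Energy ties are broken lexicographically by the torsions
#' rounded to 0.1 degree, which also makes the merge independent of input
#' order.
#'
#' @param results a `grid_search_result` (or its `minima` data.frame).
#' @param config a [search_config()]; only `dedup_tol` and `torsions` are
#'   used.
#' @return a `conformer_table` with columns
#'   `name,R,beta,Phi,phi1,...,mu,dE,dG`: descriptors are recomputed from
#'   the surviving conformations when available, `mu` and `dG` are `NA`
#'   (quantum-chemical inputs, not computed here), `dE` is the energy
#'   relative to the best survivor.
#' @export
deduplicate_and_rank <- function(results, config = search_config()) {
  if (inherits(results, "grid_search_result")) {
    minima <- results$minima
    confs <- results$conformations
  } else {
    minima <- results
    confs <- NULL
  }
  if (!nrow(minima)) stop("no minima to deduplicate", call. = FALSE)
  tors <- intersect(config$torsions, names(minima))
  key <- do.call(paste, c(lapply(tors, function(t) {
    sprintf("%.1f", wrap_angle(round(minima[[t]], 1L)))
  }), list(sep = "/")))
  ord <- order(minima$energy_abs %||% minima$energy, key)
  minima <- minima[ord, , drop = FALSE]
  if (!is.null(confs)) confs <- confs[ord]

  reps <- integer()  # row indices of cluster representatives
  cluster_of <- integer(nrow(minima))
  for (i in seq_len(nrow(minima))) {
    hit <- 0L
    for (r in seq_along(reps)) {
      dd <- vapply(tors, function(t)
        circular_diff(minima[[t]][i], minima[[t]][reps[r]]), numeric(1L))
      if (max(dd) <= config$dedup_tol) { hit <- r; break }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      hit <- length(reps)
    }
    cluster_of[i] <- hit
  }
  surv <- minima[reps, , drop = FALSE]
  surv_conf <- if (!is.null(confs)) confs[reps] else NULL

  e <- surv$energy_abs %||% surv$energy
  rel <- e - min(e)
  phi1 <- if ("phi1" %in% names(surv)) {
    surv$phi1
  } else if (!is.null(surv_conf)) {
    # phi1 not driven: measure it on the surviving conformations
    vapply(surv_conf, measure_torsion, numeric(1L), torsion = "phi1")
  } else {
    stop("phi1 required for ranking", call. = FALSE)
  }
  cls <- ifelse(phi1 < 0, "A", ifelse(phi1 > 0, "B", "U"))
  if (any(cls == "U")) {
    warning(sum(cls == "U"),
            " minimum/minima with phi1 = 0 routed to the unclassified bucket",
            call. = FALSE)
  }
  rows <- list()
  for (cl in c("A", "B", "U")) {
    idx <- which(cls == cl)
    if (!length(idx)) next
    idx <- idx[order(rel[idx])]
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (!is.null(surv_conf)) {
        ds <- descriptor_set(surv_conf[[i]], name = paste0(cl, j))
      } else {
        ds <- data.frame(name = paste0(cl, j), R = NA_real_,
                         beta = NA_real_, Phi = NA_real_)
        for (t in names(TORSION_DEFS)) {
          ds[[t]] <- if (t %in% names(surv)) surv[[t]][i] else NA_real_
        }
      }
      ds$mu <- NA_real_
      ds$dE <- rel[i]
      ds$dG <- NA_real_
      rows[[length(rows) + 1L]] <- ds
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  new_conformer_table(out, level = "surrogate model",
                      provenance = "grid_search")
}
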