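# Scoring of naturally occurring morphogen gradients against the trade-off
# optimum. The built-in registry carries only quantities printed in the
# primary literature for the four Drosophila systems (decay lengths for Bcd,
# Wg, Hh, Dpp; boundary ranges, relative system geometry and measured
# precision where available); all other geometric fields must come from a
# user configuration and every filled value carries a provenance string.

#' A morphogen system record
#'
#' @param name system name.
#' @param lambda_um measured decay length, micrometers.
#' @param xb_rel_lo,xb_rel_hi target-boundary range as a fraction of the
#'   patterned length.
#' @param L_um patterned system length, micrometers (optional).
#' @param lcell_um cell length, micrometers (optional; also used as the
#'   sensor size proxy: half-width \code{a = lcell_um/2}).
#' @param L_over_lcell ratio L/lcell (optional; derived if both lengths are
#'   present).
#' @param epsilon_sq_measured experimentally measured squared relative
#'   positional error at the boundary (optional).
#' @param provenance named character vector mapping field names to a
#'   provenance note (e.g. "printed", "user").
#' @return object of class \code{"morphogen_record"}.
#' @export
morphogen_record <- function(name, lambda_um, xb_rel_lo, xb_rel_hi,
                             L_um = NA_real_, lcell_um = NA_real_,
                             L_over_lcell = NA_real_,
                             epsilon_sq_measured = NA_real_,
                             provenance = character()) {
  if (!is.finite(lambda_um) || lambda_um <= 0) {
    stop("invalid parameter: lambda_um must be positive")
  }
  if (any(c(xb_rel_lo, xb_rel_hi) <= 0) || any(c(xb_rel_lo, xb_rel_hi) >= 1) ||
      xb_rel_lo > xb_rel_hi) {
    stop("invalid parameter: require 0 < xb_rel_lo <= xb_rel_hi < 1")
  }
  if (is.na(L_over_lcell) && is.finite(L_um) && is.finite(lcell_um)) {
    L_over_lcell <- L_um / lcell_um
    provenance["L_over_lcell"] <- "derived"
  }
  structure(list(name = name, lambda_um = lambda_um,
                 xb_rel_lo = xb_rel_lo, xb_rel_hi = xb_rel_hi,
                 L_um = L_um, lcell_um = lcell_um,
                 L_over_lcell = L_over_lcell,
                 epsilon_sq_measured = epsilon_sq_measured,
                 provenance = provenance),
            class = "morphogen_record")
}

#' @export
print.morphogen_record <- function(x, ...) {
  cat(sprintf("%s: lambda = %g um, xb in [%.2f, %.2f] L", x$name,
              x$lambda_um, x$xb_rel_lo, x$xb_rel_hi))
  if (is.finite(x$L_um)) cat(sprintf(", L = %g um", x$L_um))
  if (is.finite(x$epsilon_sq_measured)) {
    cat(sprintf(", eps^2 = %g", x$epsilon_sq_measured))
  }
  cat("\n")
  invisible(x)
}

# built-in registry: printed values only
.atlas_builtin <- function() {
  pr <- function(...) {
    v <- c(...)
    stats::setNames(rep("printed", length(v)), v)
  }
  list(
    Bcd = morphogen_record(
      "Bcd", lambda_um = 100, xb_rel_lo = 0.4, xb_rel_hi = 0.5,
      L_um = 500, L_over_lcell = 50, epsilon_sq_measured = 7e-4,
      provenance = pr("lambda_um", "xb_rel_lo", "xb_rel_hi", "L_um",
                      "L_over_lcell", "epsilon_sq_measured")),
    Wg = morphogen_record(
      "Wg", lambda_um = 6, xb_rel_lo = 0.4, xb_rel_hi = 0.5,
      provenance = c(pr("lambda_um"),
                     xb_rel_lo = "assumed-midrange", xb_rel_hi = "assumed-midrange")),
    Hh = morphogen_record(
      "Hh", lambda_um = 8, xb_rel_lo = 0.4, xb_rel_hi = 0.5,
      provenance = c(pr("lambda_um"),
                     xb_rel_lo = "assumed-midrange", xb_rel_hi = "assumed-midrange")),
    Dpp = morphogen_record(
      "Dpp", lambda_um = 20, xb_rel_lo = 0.4, xb_rel_hi = 0.5,
      epsilon_sq_measured = 1.5e-2,
      provenance = pr("lambda_um", "xb_rel_lo", "xb_rel_hi",
                      "epsilon_sq_measured"))
  )
}

#' Load the morphogen atlas
#'
#' Returns the built-in records for Bcd, Wg, Hh and Dpp, optionally merged
#' with a YAML configuration that overrides or completes fields (geometric
#' fields absent from the registry are never invented; they must come from
#' the config). Config-supplied values get provenance \code{"user"} unless
#' the config says otherwise.
#'
#' Config layout: a top-level \code{morphogens} map of
#' \code{name: {field: value, ...}} entries; an optional per-entry
#' \code{provenance} map overrides the default \code{"user"} notes.
#'
#' @param config path to a YAML file, or a pre-parsed list, or \code{NULL}
#'   (defaults only).
#' @return named list of [morphogen_record()] objects.
#' @export
load_atlas <- function(config = NULL) {
  records <- .atlas_builtin()
  if (is.null(config)) return(records)
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    tryCatch(yaml::read_yaml(config),
             error = function(e) stop("malformed atlas config '", config,
                                      "': ", conditionMessage(e)))
  } else config
  entries <- cfg$morphogens
  if (is.null(entries)) stop("malformed atlas config: no 'morphogens' block")
  known <- c("lambda_um", "xb_rel_lo", "xb_rel_hi", "L_um", "lcell_um",
             "L_over_lcell", "epsilon_sq_measured")
  for (nm in names(entries)) {
    e <- entries[[nm]]
    prov_over <- e$provenance
    e$provenance <- NULL
    if (length(bad <- setdiff(names(e), known))) {
      stop("malformed atlas config: unknown field(s) ",
           paste(bad, collapse = ", "), " for '", nm, "'")
    }
    base <- records[[nm]]
    if (is.null(base)) {
      fields <- e
      prov <- character()
    } else {
      fields <- base[known]
      prov <- base$provenance
      # drop the derived ratio so the constructor recomputes it
      if (identical(unname(prov["L_over_lcell"]), "derived")) {
        fields$L_over_lcell <- NULL
      }
      fields[names(e)] <- e
    }
    prov[names(e)] <- "user"
    if (!is.null(prov_over)) prov[names(prov_over)] <- unlist(prov_over)
    records[[nm]] <- do.call(
      morphogen_record, c(list(name = nm), fields, list(provenance = prov)))
  }
  records
}

.require_fields <- function(record, fields) {
  for (f in fields) {
    v <- record[[f]]
    if (is.null(v) || !is.finite(v)) {
      stop("missing-parameter error: record '", record$name,
           "' lacks field '", f, "' required by this measurement model")
    }
  }
}

#' Score a morphogen system against the trade-off optimum
#'
#' Computes the normalized trade-off product, the optimal decay length and
#' the ratio \eqn{\lambda/\lambda_{min}} at the record's boundary midpoint,
#' plus the same quantities at the endpoints of the printed boundary range.
#' The point model needs the relative geometry (\code{L_um} or, with
#' \code{lcell_um}, the ratio \code{L_over_lcell}); the space-time model
#' needs \code{L_um} and the sensor proxy \code{lcell_um} (sensor half-width
#' \code{a = lcell_um/2}).
#'
#' @param record a [morphogen_record()].
#' @param model \code{"point"} or \code{"spacetime"}.
#' @return object of class \code{"optimality_score"}: list with
#'   \code{pi_normalized}, \code{pi_min_normalized}, \code{lambda_min}
#'   (same units as the boundary coordinate), \code{lambda_ratio},
#'   \code{measurement_model}, and a data frame \code{range} over (lo, mid,
#'   hi) boundary positions.
#' @export
evaluate_optimality <- function(record, model = c("point", "spacetime")) {
  stopifnot(inherits(record, "morphogen_record"))
  model <- match.arg(model)
  xb_rel <- c(lo = record$xb_rel_lo,
              mid = (record$xb_rel_lo + record$xb_rel_hi) / 2,
              hi = record$xb_rel_hi)
  if (model == "point") {
    .require_fields(record, "L_um")
    L <- record$L_um
    lam <- record$lambda_um
    one <- function(xb) {
      opt <- optimal_lambda_point(xb, L)
      c(pi = point_product_normalized(xb, lam, L),
        pi_min = opt$product_min, lambda_min = opt$lambda_min)
    }
  } else {
    .require_fields(record, c("L_um", "lcell_um"))
    L <- record$L_um
    lam <- record$lambda_um
    a <- record$lcell_um / 2
    one <- function(xb) {
      opt <- optimal_lambda_spacetime(xb, a)
      c(pi = spacetime_product_normalized(xb, lam, a),
        pi_min = opt$product_min, lambda_min = opt$lambda_min)
    }
  }
  vals <- vapply(xb_rel * L, one, numeric(3))
  mid <- vals[, "mid"]
  structure(
    list(name = record$name,
         pi_normalized = unname(mid["pi"]),
         pi_min_normalized = unname(mid["pi_min"]),
         lambda_min = unname(mid["lambda_min"]),
         lambda_ratio = lam / unname(mid["lambda_min"]),
         measurement_model = model,
         range = data.frame(position = colnames(vals),
                            xb_um = unname(xb_rel * L),
                            pi_normalized = unname(vals["pi", ]),
                            pi_min_normalized = unname(vals["pi_min", ]),
                            lambda_min = unname(vals["lambda_min", ]),
                            lambda_ratio = lam / unname(vals["lambda_min", ]))),
    class = "optimality_score"
  )
}

#' @export
print.optimality_score <- function(x, ...) {
  cat(sprintf("%s (%s model): pi = %.4g (min %.4g), lambda/lambda_min = %.3f\n",
              x$name, x$measurement_model, x$pi_normalized,
              x$pi_min_normalized, x$lambda_ratio))
  invisible(x)
}

#' Cost of a morphogen profile from its trade-off product and precision
#'
#' Divides the trade-off product at the boundary by the experimentally
#' measured squared positional error:
#' \eqn{C = \pi_o(x_b;\lambda)/\epsilon^2 =
#' \alpha_o (L/l_{cell})\,\pi_{norm}/\epsilon^2}. For Bicoid
#' (\eqn{x_b = 0.4L}, \eqn{\lambda = 0.2L}, \eqn{L/l_{cell} = 50},
#' \eqn{\epsilon^2 = 7\times10^{-4}}) this gives about \eqn{4\times10^4}
#' molecule-equivalents.
#'
#' @param record a [morphogen_record()] with \code{epsilon_sq_measured},
#'   \code{L_over_lcell} and \code{L_um} available.
#' @param alpha_o per-molecule cost in ATP (default 2e3, the Bicoid
#'   estimate).
#' @param xb_rel boundary position as fraction of L (default: the record's
#'   lower bound, the printed Bcd working point).
#' @return list with \code{cost_alpha_units} and \code{cost_ATP}.
#' @export
bcd_cost_estimate <- function(record, alpha_o = 2e3,
                              xb_rel = record$xb_rel_lo) {
  stopifnot(inherits(record, "morphogen_record"))
  .require_fields(record, c("epsilon_sq_measured", "L_over_lcell", "L_um"))
  pi_norm <- point_product_normalized(xb_rel * record$L_um,
                                      record$lambda_um, record$L_um)
  cost_alpha <- pi_norm * record$L_over_lcell / record$epsilon_sq_measured
  list(cost_alpha_units = cost_alpha, cost_ATP = cost_alpha * alpha_o,
       pi_normalized = pi_norm)
}

#' Total ATP bookkeeping of ambient morphogen production
#'
#' Multiplies a measured number of produced molecules by the per-molecule
#' cost; e.g. 5e8 Bicoid molecules at alpha_o = 494 amino acids x 4
#' ATP/bond = 1976 ATP gives about 1e12 ATP.
#'
#' @param n_molecules number of molecules produced.
#' @param alpha_o per-molecule ATP cost.
#' @return total ATP equivalents.
#' @export
ambient_production_estimate <- function(n_molecules, alpha_o) {
  if (n_molecules < 0 || alpha_o <= 0) {
    stop("invalid parameter: need n_molecules >= 0, alpha_o > 0")
  }
  n_molecules * alpha_o
}

#' Write atlas scores to disk
#'
#' Emits a CSV table (one row per morphogen x model) and a JSON summary;
#' optionally a heatmap of the trade-off product over (xb, lambda) with the
#' optimal-lambda curve (requires ggplot2). Output is deterministic given
#' identical inputs.
#'
#' @param scores list of \code{"optimality_score"} objects.
#' @param out_dir output directory (created if missing).
#' @param heatmap logical; draw the point-model product heatmap.
#' @return invisibly, the paths written.
#' @export
atlas_report <- function(scores, out_dir, heatmap = FALSE) {
  if (length(scores) == 0) stop("invalid parameter: empty score list")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- do.call(rbind, lapply(scores, function(s) {
    data.frame(name = s$name, model = s$measurement_model,
               pi_normalized = s$pi_normalized,
               pi_min_normalized = s$pi_min_normalized,
               lambda_min = s$lambda_min, lambda_ratio = s$lambda_ratio)
  }))
  csv_path <- file.path(out_dir, "atlas_scores.csv")
  utils::write.csv(tab, csv_path, row.names = FALSE)
  json_path <- file.path(out_dir, "atlas_scores.json")
  jsonlite::write_json(
    lapply(unname(scores), function(s) s[c("name", "measurement_model",
                                   "pi_normalized", "pi_min_normalized",
                                   "lambda_min", "lambda_ratio")]),
    json_path, auto_unbox = TRUE, digits = NA)
  paths <- c(csv_path, json_path)
  if (heatmap && requireNamespace("ggplot2", quietly = TRUE)) {
    xb <- seq(0.05, 0.6, length.out = 60)
    lam <- seq(0.02, 0.6, length.out = 60)
    grid <- expand.grid(xb = xb, lam = lam)
    grid$logpi <- log10(point_product_normalized(grid$xb, grid$lam, 1))
    curve <- data.frame(
      xb = xb,
      lam_min = vapply(xb, function(x) optimal_lambda_point(x, 1)$lambda_min,
                       numeric(1)))
    p <- ggplot2::ggplot(grid, ggplot2::aes(x = xb, y = lam, fill = logpi)) +
      ggplot2::geom_raster() +
      ggplot2::geom_line(data = curve,
                         ggplot2::aes(x = xb, y = lam_min),
                         inherit.aes = FALSE) +
      ggplot2::labs(x = "xb / L", y = "lambda / L",
                    fill = "log10 pi / (alpha_o L/lcell)")
    png_path <- file.path(out_dir, "tradeoff_heatmap.png")
    ggplot2::ggsave(png_path, p, width = 6, height = 4, dpi = 150)
    paths <- c(paths, png_path)
  }
  invisible(paths)
}
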