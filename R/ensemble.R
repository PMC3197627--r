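# Ensemble pooling and mutant-vs-wildtype comparisons.

variable_column <- function(variable) {
  switch(variable, shift = "z_shift", tilt = "tilt", rotation = "rotation",
         abort("variable must be one of shift, tilt, rotation"))
}

default_binwidth <- function(variable) {
  switch(variable, shift = 0.25, tilt = 1, rotation = 5)
}

tm_values <- function(geometry, variable) {
  col <- variable_column(variable)
  keep <- geometry$is_tm & geometry$bilayer_ok
  if (variable == "rotation") keep <- keep & geometry$rotation_defined
  list(values = geometry[[col]][keep], n_excluded = sum(!keep),
       replicas = geometry$replica[keep])
}

#' Pool per-frame geometry into an ensemble distribution
#'
#' Pools all transmembrane frames of all replicas into one histogram
#' (interfacial and bilayer-less frames are excluded and counted). Default
#' bin widths: 0.25 A (shift), 1 deg (tilt), 5 deg (rotation). Rotation is
#' treated circularly: mean, mode and sd are circular statistics and bins
#' span [-180, 180).
#'
#' @param geometry tibble from [trajectory_geometry()]/[ensemble_geometry()].
#' @param variable `"shift"`, `"tilt"` or `"rotation"`.
#' @param binwidth histogram bin width; default per variable.
#' @return object of class `ensemble_distribution`.
#' @export
pool_geometry <- function(geometry, variable = "shift", binwidth = NULL) {
  v <- tm_values(geometry, variable)
  if (!length(v$values))
    abort("no transmembrane frames to pool: empty distribution")
  if (is.null(binwidth)) binwidth <- default_binwidth(variable)
  circular <- variable == "rotation"
  x <- v$values
  if (circular) {
    breaks <- seq(-180, 180, by = binwidth)
    if (tail(breaks, 1) < 180) breaks <- c(breaks, 180)
  } else {
    breaks <- seq(floor(min(x) / binwidth) * binwidth,
                  ceiling(max(x) / binwidth) * binwidth + binwidth / 2,
                  by = binwidth)
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  mode_ <- h$mids[which.max(h$counts)]
  structure(list(
    variable = variable,
    breaks = h$breaks, counts = h$counts, mids = h$mids,
    mean = if (circular) circ_mean_deg(x) else mean(x),
    mode = mode_,
    sd = if (circular) circ_sd_deg(x) else sd(x),
    circular = circular,
    n_frames = nrow(geometry),
    n_used = length(x),
    n_excluded = v$n_excluded,
    n_replicas = length(unique(v$replicas[!is.na(v$replicas)]))
  ), class = "ensemble_distribution")
}

#' @export
print.ensemble_distribution <- function(x, ...) {
  unit <- if (x$variable == "shift") "A" else "deg"
  cat("<ensemble_distribution> ", x$variable, ": mean ",
      sprintf("%.3f", x$mean), " ", unit, " (sd ", sprintf("%.3f", x$sd),
      "), mode ", sprintf("%.3f", x$mode), "; ", x$n_used, "/", x$n_frames,
      " frames pooled (", x$n_excluded, " excluded) from ", x$n_replicas,
      " replicas\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ensemble_distribution <- function(x, ...) {
  tibble(variable = x$variable, bin_mid = x$mids, count = x$counts,
         density = x$counts / sum(x$counts) / diff(x$breaks))
}

#' @export
glance.ensemble_distribution <- function(x, ...) {
  tibble(variable = x$variable, mean = x$mean, mode = x$mode, sd = x$sd,
         circular = x$circular, n_used = x$n_used, n_frames = x$n_frames,
         n_excluded = x$n_excluded, n_replicas = x$n_replicas)
}

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_vline labs theme_minimal
#' @export
autoplot.ensemble_distribution <- function(object, ...) {
  d <- tidy(object)
  unit <- if (object$variable == "shift") "(Å)" else "(deg)"
  ggplot(d, aes(x = .data$bin_mid, y = .data$density)) +
    geom_col(width = diff(object$breaks)[1], fill = "grey35") +
    geom_vline(xintercept = object$mean, colour = "red", linetype = 2) +
    labs(x = paste(object$variable, unit), y = "density") +
    theme_minimal()
}

delta_stat <- function(xm, xw, circular) {
  if (circular) circ_diff_deg(circ_mean_deg(xm), circ_mean_deg(xw))
  else mean(xm) - mean(xw)
}

boot_delta <- function(vm, vw, circular, n_boot) {
  rm_ <- unique(vm$replicas); rw <- unique(vw$replicas)
  vapply(seq_len(n_boot), function(b) {
    sm <- sample(rm_, length(rm_), replace = TRUE)
    sw <- sample(rw, length(rw), replace = TRUE)
    xm <- unlist(lapply(sm, function(r) vm$values[vm$replicas == r]))
    xw <- unlist(lapply(sw, function(r) vw$values[vw$replicas == r]))
    if (!length(xm) || !length(xw)) return(NA_real_)
    delta_stat(xm, xw, circular)
  }, numeric(1))
}

#' Compare a mutant ensemble against wildtype
#'
#' Computes mutant-minus-wildtype differences of the pooled means for shift,
#' tilt and rotation (shortest-arc circular difference for rotation), with
#' percentile bootstrap confidence intervals resampling replicas, not frames
#' (frames within a replica are autocorrelated; a frame-level bootstrap is
#' refused). The shift difference carries a direction label under the sign
#' convention positive = periplasmic.
#'
#' @param mutant,wildtype geometry tibbles ([ensemble_geometry()]), with
#'   non-missing `replica` labels.
#' @param variables which of shift/tilt/rotation to compare.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @return tibble, one row per variable: delta, conf_lo, conf_hi, direction
#'   (shift only), n-counts.
#' @export
compare_to_wildtype <- function(mutant, wildtype,
                                variables = c("shift", "tilt", "rotation"),
                                n_boot = 500, conf = 0.95) {
  if (anyNA(mutant$replica) || anyNA(wildtype$replica))
    abort("replica labels are required: refusing a frame-level bootstrap")
  rows <- lapply(variables, function(variable) {
    vm <- tm_values(mutant, variable)
    vw <- tm_values(wildtype, variable)
    if (!length(vm$values) || !length(vw$values))
      abort(paste0("no transmembrane frames for variable ", variable))
    circular <- variable == "rotation"
    delta <- delta_stat(vm$values, vw$values, circular)
    bd <- boot_delta(vm, vw, circular, n_boot)
    a <- (1 - conf) / 2
    ci <- quantile(bd, c(a, 1 - a), na.rm = TRUE, names = FALSE)
    tibble(variable = variable, delta = delta,
           conf_lo = ci[1], conf_hi = ci[2],
           direction = if (variable == "shift") {
             if (delta >= 0) "periplasmic" else "cytoplasmic"
           } else NA_character_,
           n_mutant = length(vm$values), n_wildtype = length(vw$values),
           n_replicas_mutant = length(unique(vm$replicas)),
           n_replicas_wildtype = length(unique(vw$replicas)))
  })
  bind_rows(rows)
}

#' Phenotype summary across a mutant set
#'
#' One row per mutant with its kinase-phenotype label and the mutant-minus-
#' wildtype shift/tilt/rotation differences with bootstrap confidence
#' intervals, plus the rank correlation (Spearman) between the phenotype
#' ordering (kinase_inactive < wildtype/mixed < kinase_active) and the shift
#' difference. With fewer than 2 mutants the correlation is undefined and
#' flagged NA.
#'
#' @param geometries named list of geometry tibbles, one per peptide id.
#' @param peptides peptide tibble with id and phenotype columns.
#' @param wildtype_id id of the wildtype ensemble in `geometries`.
#' @param n_boot bootstrap resamples per comparison.
#' @return object of class `phenotype_report`: `$table` (tibble) and
#'   `$shift_phenotype_correlation`.
#' @export
phenotype_report <- function(geometries, peptides, wildtype_id,
                             n_boot = 500) {
  if (!wildtype_id %in% names(geometries))
    abort("wildtype ensemble not found in geometries")
  wt <- geometries[[wildtype_id]]
  ids <- setdiff(names(geometries), wildtype_id)
  rows <- lapply(ids, function(id) {
    cmp <- compare_to_wildtype(geometries[[id]], wt, n_boot = n_boot)
    w <- tidyr::pivot_wider(
      select(cmp, "variable", "delta", "conf_lo", "conf_hi"),
      names_from = "variable",
      values_from = c("delta", "conf_lo", "conf_hi"))
    w$id <- id
    w$phenotype <- peptides$phenotype[match(id, peptides$id)]
    w$shift_direction <- cmp$direction[cmp$variable == "shift"]
    w
  })
  tab <- bind_rows(rows)
  ord <- c(kinase_inactive = -1, mixed = 0, wildtype = 0, kinase_active = 1)
  tab$phenotype_rank <- ord[tab$phenotype]
  corr <- if (nrow(tab) >= 2 && length(unique(tab$phenotype_rank)) > 1) {
    suppressWarnings(cor(tab$phenotype_rank, tab$delta_shift, method = "spearman"))
  } else NA_real_
  tab <- select(tab, "id", "phenotype", "phenotype_rank", "delta_shift",
                "conf_lo_shift", "conf_hi_shift", "shift_direction",
                "delta_tilt", "conf_lo_tilt", "conf_hi_tilt",
                "delta_rotation", "conf_lo_rotation", "conf_hi_rotation")
  structure(list(table = tab, shift_phenotype_correlation = corr,
                 wildtype_id = wildtype_id),
            class = "phenotype_report")
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat("<phenotype_report> vs ", x$wildtype_id, "; Spearman(phenotype, delta shift) = ",
      if (is.na(x$shift_phenotype_correlation)) "NA (undefined)" else
        sprintf("%.2f", x$shift_phenotype_correlation), "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @export
tidy.phenotype_report <- function(x, ...) x$table

#' @export
glance.phenotype_report <- function(x, ...) {
  tibble(wildtype_id = x$wildtype_id, n_mutants = nrow(x$table),
         shift_phenotype_correlation = x$shift_phenotype_correlation)
}

#' @importFrom ggplot2 geom_pointrange geom_hline scale_colour_manual
#' @export
autoplot.phenotype_report <- function(object, ...) {
  d <- object$table
  d$id <- factor(d$id, levels = d$id[order(d$delta_shift)])
  ggplot(d, aes(x = .data$id, y = .data$delta_shift, colour = .data$phenotype)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_pointrange(aes(ymin = .data$conf_lo_shift, ymax = .data$conf_hi_shift)) +
    scale_colour_manual(values = c(kinase_inactive = "red", wildtype = "black",
                                   mixed = "purple", kinase_active = "blue")) +
    labs(x = NULL, y = "shift vs wildtype (Å)") +
    theme_minimal()
}
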