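# Reporting layer: per-level summary tables (percent scale, two decimals,
# final row starred), the cases/controls-per-cell bar-chart figure, and a
# versioned JSON serialization of fits so saved models can be reloaded for
# prediction and inference.

#' Summarize an MDR fit per interaction level
#'
#' One row per interaction level with the best locus combination and its
#' accuracies (percent, two decimals).  Cross-validation fits report
#' classification accuracy, prediction accuracy and cross-validation
#' consistency; three-way split fits report training, testing and
#' validation accuracy.  The selected final model's row is starred when
#' printed.
#'
#' @param object an `mdr_fit`.
#' @param ... unused.
#' @return A `summary.mdr_fit` object: the underlying data frame plus the
#'   final-level marker.
#' @export
summary.mdr_fit <- function(object, ...) {
  tab <- object$table
  if (object$scheme == "cv") {
    df <- data.frame(
      Level = tab$level,
      `Best Models` = tab$model,
      `Classification Accuracy` = round(100 * tab$classification, 2),
      `Prediction Accuracy` = round(100 * tab$prediction, 2),
      `Cross-Validation Consistency` = tab$consistency,
      check.names = FALSE
    )
  } else {
    df <- data.frame(
      Level = tab$level,
      `Best Models` = tab$model,
      `Training Accuracy` = round(100 * tab$training, 2),
      `Testing Accuracy` = round(100 * tab$testing, 2),
      `Validation Accuracy` = round(100 * tab$validation, 2),
      check.names = FALSE
    )
  }
  structure(list(table = df, final_level = object$final_level,
                 scheme = object$scheme),
            class = "summary.mdr_fit")
}

#' @export
print.summary.mdr_fit <- function(x, ...) {
  shown <- cbind(` ` = ifelse(x$table$Level == x$final_level, "*", ""),
                 x$table)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.summary.mdr_fit <- function(x, ...) x$table

#' Write an MDR summary table as TSV
#'
#' Tab-separated with the table's header row; re-reading with
#' `read.delim(check.names = FALSE)` reproduces the data frame.
#'
#' @param x a `summary.mdr_fit` (or an `mdr_fit`, summarized first).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_mdr_summary <- function(x, file) {
  if (inherits(x, "mdr_fit")) x <- summary(x)
  stopifnot(inherits(x, "summary.mdr_fit"))
  utils::write.table(x$table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Per-cell counts behind the final-model figure
#'
#' Long-format data frame with one row per genotype cell and status group:
#' the genotype code at each model locus, the case/control count, and the
#' cell's risk label.  This is the exact data series drawn by
#' [plot.mdr_fit()].
#'
#' @param fit an `mdr_fit`.
#' @return Data frame with columns `<locus name>` (one per model locus),
#'   `group` (`"Case"`/`"Control"`), `count` and `risk`
#'   (`"HIGH"`/`"LOW"`/`"EMPTY"`).
#' @export
cell_counts <- function(fit) {
  stopifnot(inherits(fit, "mdr_fit"))
  cells <- fit$cells
  model <- fit$final_model
  k <- length(cells$loci)
  L <- length(cells$levels)
  g <- .decode_key(seq_len(L^k), k, L)
  risk <- ifelse(!model$observed, "EMPTY",
                 ifelse(model$high, "HIGH", "LOW"))
  geno <- as.data.frame(matrix(cells$levels[g + 1L], ncol = k))
  colnames(geno) <- cells$locus_names
  out <- rbind(cbind(geno, group = "Case", count = cells$ca, risk = risk),
               cbind(geno, group = "Control", count = cells$co, risk = risk))
  rownames(out) <- NULL
  out
}

#' Plot cases and controls per genotype cell of the final model
#'
#' A contingency grid of bar charts: one panel per genotype combination of
#' the final model's loci (up to three), two bars per panel (cases and
#' controls), with high-risk cells shaded and never-observed cells left
#' empty.
#'
#' @param x an `mdr_fit` whose final model has at most three loci.
#' @param ... unused.
#' @return A ggplot object (print or [ggplot2::ggsave()] it).
#' @export
plot.mdr_fit <- function(x, ...) {
  df <- cell_counts(x)
  nm <- x$cells$locus_names
  k <- length(nm)
  if (k > 3L)
    stop("the cell grid is drawn for final models of at most 3 loci")
  lab <- function(j) {
    f <- paste0("Locus ", nm[j], " = ", df[[j]])
    factor(f, levels = unique(f[order(df[[j]])]))
  }
  df$.gx <- lab(1L)
  if (k >= 2L) df$.gy <- lab(2L)
  if (k == 3L) df$.gz <- lab(3L)
  shade <- df[df$group == "Case", , drop = FALSE]
  facet <- switch(k,
    ggplot2::facet_grid(cols = ggplot2::vars(.data$.gx)),
    ggplot2::facet_grid(rows = ggplot2::vars(.data$.gy),
                        cols = ggplot2::vars(.data$.gx)),
    ggplot2::facet_grid(rows = ggplot2::vars(.data$.gy),
                        cols = ggplot2::vars(.data$.gz, .data$.gx)))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(fill = .data$risk),
                       xmin = -Inf, xmax = Inf, ymin = -Inf, ymax = Inf,
                       alpha = 0.25) +
    ggplot2::geom_col(ggplot2::aes(x = .data$group, y = .data$count),
                      fill = "grey25", width = 0.6) +
    ggplot2::scale_fill_manual(values = c(HIGH = "orange", LOW = "skyblue",
                                          EMPTY = "white"),
                               name = "Cell risk") +
    facet +
    ggplot2::labs(x = NULL, y = "Count",
                  title = paste("Cases and controls per genotype cell:",
                                paste(nm, collapse = " x "))) +
    ggplot2::theme_bw()
}

#' Draw the final-model cell figure to a file
#'
#' @param fit an `mdr_fit`.
#' @param file output image path (extension selects the device, e.g.
#'   `.png` or `.svg`); `NULL` returns the plot without writing.
#' @param width,height device size in inches.
#' @return The ggplot object, invisibly.
#' @export
plot_cells <- function(fit, file = NULL, width = 7, height = 5) {
  pl <- plot(fit)
  if (!is.null(file))
    ggplot2::ggsave(file, pl, width = width, height = height)
  invisible(pl)
}

#' Save a fitted MDR model as JSON
#'
#' Versioned, portable serialization of an `mdr_fit`: options echo,
#' per-level table, and the final model's risk map (genotype tuple, label
#' and training counts per cell).  [read_mdr_fit()] restores an object
#' usable with [predict.mdr_fit()], [permute_fit()], [mdr_ca_adj()] and
#' [boot_error()].
#'
#' @param fit an `mdr_fit`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_mdr_fit <- function(fit, file) {
  stopifnot(inherits(fit, "mdr_fit"))
  cells <- fit$cells
  model <- fit$final_model
  k <- length(model$loci)
  L <- length(model$levels)
  g <- .decode_key(seq_len(L^k), k, L)
  obs <- which(model$observed | cells$ca + cells$co > 0L)
  risk_map <- lapply(obs, function(i) list(
    genotype = model$levels[g[i, ] + 1L],
    label = if (model$high[i]) "HIGH" else "LOW",
    n_case = cells$ca[i],
    n_control = cells$co[i]
  ))
  tab <- fit$table
  tab$loci <- NULL
  payload <- list(
    format = "mdr_fit",
    version = 1L,
    scheme = fit$scheme,
    options = fit$options,
    levels = fit$levels,
    locus_names = fit$locus_names,
    n = fit$n,
    table = tab,
    final_level = fit$final_level,
    final_model = list(
      loci = model$loci,
      threshold = model$threshold,
      equal = fit$options$equal,
      risk = risk_map
    )
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' Load a fitted MDR model from JSON
#'
#' @param file path written by [write_mdr_fit()].
#' @return An `mdr_fit` object.
#' @export
read_mdr_fit <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(x$format, "mdr_fit"))
    stop("'", file, "' is not a serialized MDR fit")
  loci <- as.integer(x$final_model$loci)
  k <- length(loci)
  L <- length(x$levels)
  ncell <- L^k
  high <- observed <- logical(ncell)
  ca <- co <- integer(ncell)
  rk <- x$final_model$risk    # data frame: genotype (list), label, counts
  for (i in seq_len(nrow(rk))) {
    codes <- match(unlist(rk$genotype[i]), x$levels) - 1L
    idx <- 1L + sum(codes * L^(seq_len(k) - 1L))
    observed[idx] <- TRUE
    high[idx] <- rk$label[i] == "HIGH"
    ca[idx] <- rk$n_case[i]
    co[idx] <- rk$n_control[i]
  }
  opt <- x$options
  opt$proportion <- if (!is.null(opt$proportion)) as.numeric(opt$proportion)
  tab <- x$table
  tab$loci <- I(lapply(strsplit(tab$model, " "),
                       function(s) match(s, x$locus_names)))
  model <- structure(list(
    loci = loci, levels = x$levels, locus_names = x$locus_names[loci],
    high = high, observed = observed,
    threshold = x$final_model$threshold,
    ratio = opt$ratio, equal = x$final_model$equal
  ), class = "mdr_risk")
  cells <- structure(list(
    loci = loci, levels = x$levels, locus_names = x$locus_names[loci],
    ca = ca, co = co, n_used = sum(ca) + sum(co), n_excluded = NA_integer_
  ), class = "mdr_cells")
  structure(list(
    scheme = x$scheme, table = tab, final_level = as.integer(x$final_level),
    final_loci = loci, final_model = model, cells = cells,
    options = opt, levels = x$levels, locus_names = x$locus_names,
    n = as.integer(x$n)
  ), class = "mdr_fit")
}
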