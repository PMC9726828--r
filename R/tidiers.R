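# broom-style accessors and ggplot2 autoplot methods for fitted objects.

#' @export
print.regulator_screen <- function(x, ...) {
  cat("Regulator screen: ", nrow(x$ranking), " TFs, ",
      x$config$n_replicates, " replicates x ",
      x$config$n_background_sets, " background sets (seed ",
      x$config$seed, ")\n", sep = "")
  if (!is.null(x$target_cutoff)) {
    cat("Target matrix cutoff: p <= ", format(x$target_cutoff), " over ",
        x$n_genes, " genes\n", sep = "")
  }
  sel <- select_top_regulators(x)
  cat("Selected at q <= ", format(x$config$q_cutoff), ": ",
      if (length(sel) == 0) "(none)" else paste(sel, collapse = ", "),
      "\n\n", sep = "")
  cols <- c("tf", "rank_product", "p_value", "q_value", "selected")
  print(head(x$ranking[, cols], 10))
  invisible(x)
}

#' Tidy a regulator screen
#'
#' One row per TF with per-replicate scores and ranks, rank product,
#' permutation p-value, q-value and selection flag, in ascending rank-product
#' order.
#'
#' @param x A `regulator_screen` from [discover_regulators()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.regulator_screen <- function(x, ...) {
  x$ranking
}

#' One-row summary of a regulator screen
#'
#' @param x A `regulator_screen`.
#' @param ... Unused.
#' @return A one-row tibble: `n_tfs`, `n_genes`, `n_replicates`,
#'   `n_background_sets`, `q_cutoff`, `n_selected`, `min_rank_product`,
#'   `min_q_value`.
#' @export
glance.regulator_screen <- function(x, ...) {
  tibble(
    n_tfs = nrow(x$ranking),
    n_genes = x$n_genes,
    n_replicates = x$config$n_replicates,
    n_background_sets = x$config$n_background_sets,
    q_cutoff = x$config$q_cutoff,
    n_selected = sum(x$ranking$selected),
    min_rank_product = min(x$ranking$rank_product),
    min_q_value = min(x$ranking$q_value)
  )
}

#' Plot a regulator screen
#'
#' Rank product per TF (ascending), coloured by whether the TF passes the
#' q-value cutoff. Consistently top-ranked regulators sit at the left with
#' rank products near 1.
#'
#' @param object A `regulator_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regulator_screen <- function(object, ...) {
  d <- object$ranking %>%
    mutate(tf = stats::reorder(.data$tf, .data$rank_product),
           status = ifelse(.data$selected == 1,
                           paste0("q ≤ ", object$config$q_cutoff),
                           "not selected"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tf, y = .data$rank_product,
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "rank product", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot called CRM around their genes' TSSs
#'
#' One horizontal segment per candidate, faceted by gene, with the distinct-TF
#' count mapped to colour.
#'
#' @param object A `crm_calls` tibble from [call_crm()].
#' @param annotation Optional annotation tibble; when given, positions are
#'   shown relative to each gene's TSS.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crm_calls <- function(object, annotation = NULL, ...) {
  d <- as_tibble(as.data.frame(object))
  if (nrow(d) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no CRM called") +
             ggplot2::theme_void())
  }
  if (!is.null(annotation)) {
    d <- d %>%
      left_join(annotation[, c("gene_id", "tss")], by = "gene_id") %>%
      mutate(x0 = .data$start - .data$tss, x1 = .data$end - .data$tss)
    xlab <- "position relative to TSS (bp)"
  } else {
    d <- d %>% mutate(x0 = .data$start, x1 = .data$end)
    xlab <- "position (bp)"
  }
  ggplot2::ggplot(d, ggplot2::aes(y = .data$name)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x0, xend = .data$x1,
                                       yend = .data$name,
                                       colour = factor(.data$n_tfs)),
                          linewidth = 3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$gene_id), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = xlab, y = NULL, colour = "distinct TFs") +
    ggplot2::theme_minimal()
}
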