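#' Compare measurement methods across cilium populations
#'
#' The full method-comparison protocol on a measurement table covering all
#' cilia with every requested method:
#'
#' 1. per-population, per-method summary (mean +/- SD of length);
#' 2. pairwise method agreement (ICC(A,1) with Landis-Koch band and
#'    Bland-Altman bias/limits) within each population;
#' 3. flat-vs-angled independent t-test per method.
#'
#' @param measurements Tibble with `cilium_id`, `method`, `length_um`,
#'   `classification` (one row per cilium x method; average replicates
#'   first with [average_replicates()]).
#' @param methods Methods to include (default: all present).
#' @param loa_mult Bland-Altman limits multiplier.
#' @param var_equal Pool variances in the t-tests (default TRUE).
#' @return An object of class `cilia_comparison` with tibbles
#'   `population_summary`, `agreement` (one row per population x method
#'   pair) and `ttests` (one row per method), plus `n_per_population`.
#' @export
compare_methods <- function(measurements, methods = NULL, loa_mult = 1.96,
                            var_equal = TRUE) {
  m <- tibble::as_tibble(measurements)
  required <- c("cilium_id", "method", "length_um", "classification")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    stop("measurements lack columns: ", paste(missing, collapse = ", "),
      call. = FALSE)
  }
  methods <- methods %||% sort(unique(m$method))
  m <- dplyr::filter(m, .data$method %in% methods)
  counts <- dplyr::count(m, .data$cilium_id)
  if (length(unique(counts$n)) > 1L || any(counts$n != length(methods))) {
    stop("every cilium must be measured once by every requested method",
      call. = FALSE)
  }

  pop_summary <- dplyr::summarise(
    dplyr::group_by(m, .data$classification, .data$method),
    n = dplyr::n(),
    mean_um = mean(.data$length_um),
    sd_um = stats::sd(.data$length_um),
    label = sprintf("%.2f ± %.2f", .data$mean_um, .data$sd_um),
    .groups = "drop"
  )

  pairs <- if (length(methods) >= 2) utils::combn(methods, 2, simplify = FALSE) else list()
  agreement <- dplyr::bind_rows(lapply(
    split(m, m$classification),
    function(pop) {
      if (length(unique(pop$cilium_id)) < 2L) return(NULL) # nothing to pair
      dplyr::bind_rows(lapply(pairs, function(pr) {
        ag <- method_agreement(pop, pr[1], pr[2], loa_mult = loa_mult)
        dplyr::bind_cols(
          tibble::tibble(classification = pop$classification[1]),
          tidy(ag)
        )
      }))
    }
  ))

  ttests <- dplyr::bind_rows(lapply(methods, function(me) {
    flat <- m$length_um[m$method == me & m$classification == "FLAT"]
    ang <- m$length_um[m$method == me & m$classification == "ANGLED"]
    if (length(flat) < 2L || length(ang) < 2L) {
      return(tibble::tibble(method = me, t = NA_real_, df = NA_real_,
        p_value = NA_real_))
    }
    tt <- ttest_independent(flat, ang, var_equal = var_equal)
    dplyr::bind_cols(tibble::tibble(method = me), dplyr::rename(tt,
      mean_flat = "mean1", sd_flat = "sd1", mean_angled = "mean2",
      sd_angled = "sd2", label_flat = "label1", label_angled = "label2"
    ))
  }))

  structure(
    list(
      population_summary = pop_summary,
      agreement = agreement,
      ttests = ttests,
      methods = methods,
      n_per_population = dplyr::count(
        dplyr::distinct(m, .data$cilium_id, .data$classification),
        .data$classification
      )
    ),
    class = "cilia_comparison"
  )
}

#' @export
print.cilia_comparison <- function(x, ...) {
  cat("Cilium length method comparison\n")
  cat("\nPopulation summary (mean ± SD, um):\n")
  print(as.data.frame(x$population_summary), row.names = FALSE)
  if (nrow(x$agreement) > 0) {
    cat("\nMethod agreement per population:\n")
    cols <- c("classification", "method_a", "method_b", "icc", "icc_label",
      "bias", "loa_low", "loa_high")
    print(as.data.frame(x$agreement[, cols]), row.names = FALSE, digits = 3)
  }
  cat("\nFlat vs angled t-tests:\n")
  cols <- intersect(c("method", "t", "df", "p_value", "label_flat",
    "label_angled"), names(x$ttests))
  print(as.data.frame(x$ttests[, cols]), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @method tidy cilia_comparison
#' @export
tidy.cilia_comparison <- function(x, ...) x$agreement

#' @method glance cilia_comparison
#' @export
glance.cilia_comparison <- function(x, ...) {
  tibble::tibble(
    n_methods = length(x$methods),
    n_cilia = sum(x$n_per_population$n),
    n_flat = sum(x$n_per_population$n[x$n_per_population$classification == "FLAT"]),
    n_angled = sum(x$n_per_population$n[x$n_per_population$classification == "ANGLED"])
  )
}

#' Write a method-comparison report to CSV files
#'
#' Emits `<prefix>_summary.csv`, `<prefix>_agreement.csv` and
#' `<prefix>_ttests.csv`.
#'
#' @param comparison A [compare_methods()] result.
#' @param out_prefix Path prefix for the output files.
#' @param header Optional `#` comment header lines for every file.
#' @return Character vector of the written paths, invisibly.
#' @export
write_comparison <- function(comparison, out_prefix, header = NULL) {
  stopifnot(inherits(comparison, "cilia_comparison"))
  paths <- paste0(out_prefix, c("_summary.csv", "_agreement.csv", "_ttests.csv"))
  write_csv_commented(comparison$population_summary, paths[1], header)
  write_csv_commented(comparison$agreement, paths[2], header)
  write_csv_commented(comparison$ttests, paths[3], header)
  invisible(paths)
}
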