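#' Read a targeted-API list file
#'
#' A comma-separated file of active-ingredient names; values may be spread
#' over any number of lines and cells. Empty cells are dropped.
#'
#' @param path Path to the CSV file.
#' @return Character vector of unique API names.
#' @export
read_api_list <- function(path) {
  tokens <- unlist(strsplit(readLines(path, warn = FALSE), ","))
  tokens <- stringr::str_trim(tokens)
  tokens <- unique(tokens[tokens != ""])
  if (length(tokens) == 0) {
    stop("API list is empty; supply at least one API name", call. = FALSE)
  }
  tokens
}

zero_fill_months <- function(df, year, keys) {
  months <- sprintf("%s%02d", year, 1:12)
  grid <- tidyr::expand_grid(
    !!!rlang::set_names(lapply(keys, function(k) unique(df[[k]])), keys),
    period = months
  )
  out <- dplyr::left_join(grid, df, by = c(keys, "period"))
  dplyr::mutate(out, mass_kg = dplyr::coalesce(.data$mass_kg, 0))
}

#' Targeted-API report tables for one region and year
#'
#' Filters contributions to the requested region and year and builds the
#' five standard views: annual total per API, monthly series per API (all
#' twelve months, zero-filled, so seasonal shapes stay comparable), and
#' per-practice, per-postcode and per-form breakdowns. APIs named in the
#' target list but absent from the data appear with 0 kg — an absent drug is
#' a result, not a hole.
#'
#' @param contributions Contribution table from [quantify()], carrying
#'   `region` and `postcode` columns.
#' @param api_list Character vector of API names, or the path of a
#'   comma-separated file of names (see [read_api_list()]).
#' @param region Region name to filter on.
#' @param year Four-digit year (character or numeric).
#' @return List of tibbles: `annual`, `monthly`, `per_practice`,
#'   `per_postcode`, `per_form`.
#' @export
targeted_report <- function(contributions, api_list, region, year) {
  if (is.character(api_list) && length(api_list) == 1 && file.exists(api_list)) {
    api_list <- read_api_list(api_list)
  }
  if (length(api_list) == 0) {
    stop("API list is empty; supply at least one API name", call. = FALSE)
  }
  year <- as.character(year)
  x <- dplyr::filter(
    contributions,
    .data$region == !!region & substr(.data$period, 1, 4) == year &
      tolower(.data$api) %in% tolower(api_list)
  )
  api_tbl <- tibble::tibble(api = api_list)
  fill_apis <- function(agg) {
    out <- dplyr::left_join(api_tbl, agg, by = "api")
    dplyr::mutate(out, mass_kg = dplyr::coalesce(.data$mass_kg, 0))
  }
  monthly <- aggregate_mass(x, c("api", "period"))
  monthly <- zero_fill_months(
    dplyr::bind_rows(monthly,
                     tibble::tibble(api = setdiff(api_list, monthly$api),
                                    period = sprintf("%s01", year),
                                    mass_kg = 0)),
    year, "api"
  )
  list(
    annual = fill_apis(aggregate_mass(x, "api")),
    monthly = dplyr::arrange(monthly, .data$api, .data$period),
    per_practice = aggregate_mass(x, c("api", "practice")),
    per_postcode = aggregate_mass(x, c("api", "postcode")),
    per_form = aggregate_mass(x, c("api", "form"))
  )
}

#' Non-targeted (single-API) spatiotemporal report
#'
#' For one API in one region: prescribed kg per postcode over the requested
#' period with each postcode's share of the region total, a zero-filled
#' monthly series per postcode across the period's year, and the split of
#' the period total across medicinal forms as percentages summing to 100.
#'
#' @param contributions Contribution table from [quantify()], carrying
#'   `region` and `postcode`.
#' @param api API name (matched case-insensitively on the grouping stem).
#' @param region Region name.
#' @param period Either a four-digit year (`"2018"`) or a six-digit month
#'   (`"201801"`); per-postcode and per-form tables cover exactly this
#'   period, the monthly series always covers the containing year.
#' @return List of tibbles: `per_postcode` (`postcode`, `mass_kg`,
#'   `share_pct`), `monthly_by_postcode`, `per_form` (`form`, `mass_kg`,
#'   `share_pct`).
#' @export
nontargeted_report <- function(contributions, api, region, period) {
  period <- as.character(period)
  stopifnot(grepl("^[0-9]{4}([0-9]{2})?$", period))
  year <- substr(period, 1, 4)
  x <- dplyr::filter(contributions,
                     .data$region == !!region & tolower(.data$api) == tolower(!!api))
  x_year <- dplyr::filter(x, substr(.data$period, 1, 4) == year)
  x_window <- if (nchar(period) == 6) {
    dplyr::filter(x, .data$period == !!period)
  } else {
    x_year
  }
  total <- sum(x_window$mass_kg)
  share <- function(agg) {
    dplyr::mutate(agg, share_pct = if (total > 0) 100 * .data$mass_kg / total
                  else NA_real_)
  }
  list(
    per_postcode = share(aggregate_mass(x_window, "postcode")),
    monthly_by_postcode = zero_fill_months(
      aggregate_mass(x_year, c("postcode", "period")), year, "postcode"
    ),
    per_form = share(aggregate_mass(x_window, "form"))
  )
}

#' Export a table or plot
#'
#' Tables export as CSV (numeric round-trip safe); plots export as PNG, EPS
#' or PDF via the ggplot2 device machinery.
#'
#' @param x A data frame (CSV) or a ggplot object (image formats).
#' @param path Output file path.
#' @param format One of `"csv"`, `"png"`, `"eps"`, `"pdf"`.
#' @param width,height Plot size in inches.
#' @return `path`, invisibly.
#' @export
export <- function(x, path, format = c("csv", "png", "eps", "pdf"),
                   width = 8, height = 5) {
  if (length(format) != 1 || !format %in% c("csv", "png", "eps", "pdf")) {
    stop("unsupported format '", paste(format, collapse = ","),
         "'; supported formats: csv, png, eps, pdf", call. = FALSE)
  }
  if (format == "csv") {
    stopifnot(is.data.frame(x))
    readr::write_csv(x, path, progress = FALSE)
  } else {
    stopifnot(inherits(x, "ggplot"))
    dev <- if (format == "eps") grDevices::cairo_ps else format
    ggplot2::ggsave(path, plot = x, device = dev, width = width,
                    height = height, units = "in")
  }
  invisible(path)
}

# Okabe-Ito: colour-blind-safe categorical palette
palette_safe <- function(n) {
  pal <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2",
           "#D55E00", "#CC79A7", "#999999")
  rep_len(pal, n)
}

#' Annual per-API bar plot
#'
#' @param annual The `annual` table from [targeted_report()].
#' @param region,year Used in the title block.
#' @return A ggplot object.
#' @export
plot_annual_totals <- function(annual, region, year) {
  ggplot2::ggplot(annual,
                  ggplot2::aes(x = stats::reorder(.data$api, .data$mass_kg),
                               y = .data$mass_kg, fill = .data$api)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = palette_safe(nrow(annual))) +
    ggplot2::labs(
      title = paste0("Prescribed mass by API, ", region, ", ", year),
      x = NULL, y = "mass (kg/year)"
    ) +
    ggplot2::theme_minimal()
}

#' Monthly per-API trend plot
#'
#' @param monthly The `monthly` table from [targeted_report()].
#' @param region,year Used in the title block.
#' @return A ggplot object.
#' @export
plot_monthly_trend <- function(monthly, region, year) {
  df <- dplyr::mutate(monthly, month = as.integer(substr(.data$period, 5, 6)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$mass_kg,
                                   colour = .data$api)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = 1:12, limits = c(1, 12)) +
    ggplot2::scale_colour_manual(
      values = palette_safe(dplyr::n_distinct(df$api))
    ) +
    ggplot2::labs(
      title = paste0("Monthly prescribed mass, ", region, ", ", year),
      x = "month", y = "mass (kg/month)", colour = "API"
    ) +
    ggplot2::theme_minimal()
}

#' Medicinal-form share plot
#'
#' @param per_form The `per_form` table from [nontargeted_report()].
#' @param api,region Used in the title block.
#' @return A ggplot object.
#' @export
plot_form_shares <- function(per_form, api, region) {
  ggplot2::ggplot(per_form, ggplot2::aes(x = "", y = .data$share_pct,
                                         fill = .data$form)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::scale_fill_manual(values = palette_safe(nrow(per_form))) +
    ggplot2::labs(
      title = paste0("Form shares of ", api, ", ", region),
      x = NULL, y = NULL, fill = "form"
    ) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5))
}
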