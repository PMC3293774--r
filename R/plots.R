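#' Plot a spacing scan
#'
#' Inter-dimer contact surface against offset, coloured by the
#' clash/contact/separated classification.
#'
#' @param object a `spacing_scan` tibble from [scan_spacings()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spacing_scan <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("autoplot requires ggplot2", call. = FALSE)
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$cs_dd,
                                       fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "cs_min"),
                        linetype = "dashed") +
    ggplot2::labs(x = "dimer-dimer offset (bp)",
                  y = expression("inter-dimer contact surface (" * ring(A)^2 * ")"),
                  fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot a DNA footprint
#'
#' Per-base-pair buried surface (top + bottom strand) with the protection
#' threshold.
#'
#' @param object a `dna_footprint` from [dna_footprint()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dna_footprint <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("autoplot requires ggplot2", call. = FALSE)
  }
  df <- object$by_bp
  df$buried <- df$buried_top + df$buried_bottom
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bp, y = .data$buried,
                                   fill = .data$protected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$buried_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "base pair",
                  y = expression("buried surface (" * ring(A)^2 * ")"),
                  fill = "protected") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
tidy.spacing_scan <- function(x, ...) as_tibble(x)

#' @export
glance.spacing_scan <- function(x, ...) {
  tibble(n_offsets = nrow(x),
         n_clash = sum(x$class == "clash"),
         n_contact = sum(x$class == "contact"),
         n_separated = sum(x$class == "separated"),
         max_contact_offset = if (any(x$class == "contact"))
           max(x$offset[x$class == "contact"]) else NA_integer_)
}

#' @export
tidy.switch_report <- function(x, ...) as_tibble(x)

#' @export
tidy.criteria_report <- function(x, ...) as_tibble(x)

#' @export
glance.criteria_report <- function(x, ...) {
  tibble(overall = attr(x, "overall"), n_pass = sum(x$pass))
}

# re-export so `autoplot(x)` works without attaching ggplot2
#' @importFrom generics tidy glance
NULL

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")
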