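# broom-style tidiers for the package's fitted objects.

#' Tidy a moderated fit
#' @param x A `moderated_fit` from [moderated_t()].
#' @param ... Unused.
#' @return The per-feature result tibble.
#' @method tidy moderated_fit
#' @export
tidy.moderated_fit <- function(x, ...) x$table

#' One-row summary of a moderated fit
#' @param x A `moderated_fit`.
#' @param ... Unused.
#' @return Tibble with the shrinkage hyperparameters and test counts.
#' @method glance moderated_fit
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble(
    d0 = x$d0, s02 = x$s02, df_resid = x$df_resid,
    n_tested = nrow(x$table), n_excluded = length(x$excluded),
    n_sig = sum(x$table$adj_p < 0.05)
  )
}

#' Tidy a log10-FE Gaussian fit
#' @param x An `fe_fit` from [fit_fe_distribution()].
#' @param ... Unused.
#' @return The histogram tibble with the fitted curve value per bin.
#' @method tidy fe_fit
#' @export
tidy.fe_fit <- function(x, ...) {
  mutate(x$histogram,
         fitted = x$amplitude * exp(-(.data$mid - x$mean)^2 / (2 * x$sd^2)))
}

#' One-row summary of a log10-FE Gaussian fit
#' @param x An `fe_fit`.
#' @param ... Unused.
#' @return Tibble with `area`, `mean`, `sd`, `rss`, `n`.
#' @method glance fe_fit
#' @export
glance.fe_fit <- function(x, ...) {
  tibble(area = x$area, mean = x$mean, sd = x$sd, rss = x$rss, n = x$n)
}

#' Tidy a filtered PCA
#' @param x An `ac4c_pca` from [pca_top_mad()].
#' @param ... Unused.
#' @return The per-sample score tibble.
#' @method tidy ac4c_pca
#' @export
tidy.ac4c_pca <- function(x, ...) x$scores

#' One-row-per-component summary of a filtered PCA
#' @param x An `ac4c_pca`.
#' @param ... Unused.
#' @return Tibble with `component`, `var_explained`, `n_features`.
#' @method glance ac4c_pca
#' @export
glance.ac4c_pca <- function(x, ...) {
  tibble(
    component = seq_along(x$var_explained),
    var_explained = x$var_explained,
    n_features = length(x$kept_features)
  )
}
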