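# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_tile geom_line
#'   geom_point geom_vline scale_fill_viridis_c labs theme_minimal
NULL

#' Plot a free-energy surface
#'
#' @param object A `gag_fes` from [free_energy_surface()].
#' @param units `"kbt"` or `"kjmol"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gag_fes
#' @export
autoplot.gag_fes <- function(object, units = c("kbt", "kjmol"), ...) {
  units <- match.arg(units)
  fill <- if (units == "kbt") "dg_kbt" else "dg_kjmol"
  lab <- if (units == "kbt") expression(Delta * G ~ "(" * k[B] * T * ")") else
    expression(Delta * G ~ "(kJ/mol)")
  ggplot(object, aes(x = .data$pc1, y = .data$pc2, fill = .data[[fill]])) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "white", name = lab) +
    labs(x = "PC1", y = "PC2") +
    theme_minimal()
}

#' Plot a residue contact probability map
#'
#' Masked (self and within-disaccharide) entries are hidden, following the
#' display convention for short chains.
#'
#' @param object A `gag_contact_map`.
#' @param show_masked Show the diagonal/first off-diagonal too.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gag_contact_map
#' @export
autoplot.gag_contact_map <- function(object, show_masked = FALSE, ...) {
  d <- if (show_masked) object else object[!object$masked, ]
  ggplot(d, aes(x = .data$residue_a, y = .data$residue_b,
                fill = .data$probability)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1), name = "P(contact)") +
    labs(x = "residue", y = "residue") +
    theme_minimal()
}

#' Plot the k-means inertia (elbow) curve
#'
#' @param object A `gag_states` from [kmeans_with_elbow()].
#' @param ... Unused.
#' @return A ggplot with the selected k marked.
#' @method autoplot gag_states
#' @export
autoplot.gag_states <- function(object, ...) {
  ggplot(object$inertia, aes(x = .data$k, y = .data$inertia)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = object$k, linetype = "dashed") +
    labs(x = "number of clusters k", y = "inertia") +
    theme_minimal()
}

#' Plot a cluster-count evolution curve
#'
#' @param object A `gag_cluster_evolution` from [cluster_count_evolution()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gag_cluster_evolution
#' @export
autoplot.gag_cluster_evolution <- function(object, ...) {
  ggplot(object, aes(x = .data$checkpoint, y = .data$n_clusters)) +
    geom_line() + geom_point() +
    labs(x = "frames considered", y = "number of clusters") +
    theme_minimal()
}

#' Plot a radial distribution function
#'
#' @param object A `gag_rdf` from [radial_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gag_rdf
#' @export
autoplot.gag_rdf <- function(object, ...) {
  ggplot(object, aes(x = .data$r, y = .data$g)) +
    geom_line() +
    labs(x = "r (nm)", y = "g(r)") +
    theme_minimal()
}
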