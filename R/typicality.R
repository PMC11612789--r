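# Typicality coefficients, typicality categories, and the final assignment
# of discrete and graded call types.

#' Typicality coefficient of each call
#'
#' The typicality coefficient is the largest membership value minus the
#' second-largest: near 1 for calls prototypical of one cluster, near 0 for
#' graded or ambiguous calls lying between clusters.
#'
#' @param U membership matrix (rows sum to 1).
#' @return numeric vector in \[0, 1\].
#' @export
typicality_coefficients <- function(U) {
  U <- as.matrix(U)
  if (ncol(U) < 2) stop("need at least two clusters")
  apply(U, 1, function(u) {
    s <- sort(u, decreasing = TRUE)
    s[1] - s[2]
  })
}

#' Typicality and atypicality thresholds
#'
#' The default method places the atypicality and typicality thresholds at
#' the lower and upper terciles of the observed coefficient distribution; a
#' fixed-constant method returns user-supplied thresholds verbatim.
#'
#' @param coefficients typicality coefficients (>= 10 values for the
#'   tercile method).
#' @param method `"terciles"` or `"fixed"`.
#' @param fixed thresholds `c(atypical, typical)` for the fixed method.
#' @return list with `atypical` and `typical`, `atypical < typical`.
#' @export
compute_thresholds <- function(coefficients, method = c("terciles", "fixed"),
                               fixed = c(0.2, 0.5)) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (fixed[1] >= fixed[2]) stop("atypicality threshold must be below typicality threshold")
    return(list(atypical = fixed[1], typical = fixed[2], method = method))
  }
  if (length(coefficients) < 10) stop("need at least 10 coefficients")
  if (diff(range(coefficients)) < 1e-12) {
    stop("degenerate coefficient distribution (all values equal)")
  }
  q <- stats::quantile(coefficients, c(1 / 3, 2 / 3), names = FALSE)
  if (q[1] >= q[2]) stop("degenerate coefficient distribution (tied terciles)")
  list(atypical = q[1], typical = q[2], method = method)
}

#' Categorize calls by typicality
#'
#' Calls with coefficients strictly above the typicality threshold are
#' typical, strictly below the atypicality threshold atypical, and otherwise
#' neither (boundary values fall in "neither", matching the strict
#' higher/lower rules).
#'
#' @param coefficients typicality coefficients.
#' @param thresholds a [compute_thresholds()] result.
#' @return factor with levels atypical, neither, typical.
#' @export
categorize_typicality <- function(coefficients, thresholds) {
  if (thresholds$atypical >= thresholds$typical) {
    stop("invalid thresholds: atypical must be below typical")
  }
  out <- ifelse(coefficients > thresholds$typical, "typical",
         ifelse(coefficients < thresholds$atypical, "atypical", "neither"))
  factor(out, levels = c("atypical", "neither", "typical"))
}

#' Identify the acoustic role of each cluster
#'
#' Automates the reading of the cluster solution so the pipeline runs
#' unsupervised: the cluster with the lowest mean voiced percentage is the
#' noisy (screech) cluster; of the remaining two tonal clusters the one with
#' the shorter mean duration is the short-tonal (chirp) cluster and the
#' other the long-tonal (scream) cluster.
#'
#' @param hard_labels integer cluster labels.
#' @param voiced_percentage,duration per-call values aligned with the
#'   labels.
#' @return named character vector mapping cluster index to role
#'   (`"long_tonal"`, `"noisy"`, `"short_tonal"`).
#' @export
identify_cluster_roles <- function(hard_labels, voiced_percentage, duration) {
  cl <- sort(unique(hard_labels))
  if (length(cl) != 3) stop("role identification expects exactly 3 clusters, got ",
                            length(cl))
  mean_vp <- vapply(cl, function(k) mean(voiced_percentage[hard_labels == k],
                                         na.rm = TRUE), 0)
  mean_dur <- vapply(cl, function(k) mean(duration[hard_labels == k],
                                          na.rm = TRUE), 0)
  roles <- rep(NA_character_, 3)
  noisy <- which.min(mean_vp)
  roles[noisy] <- "noisy"
  rest <- setdiff(seq_along(cl), noisy)
  chirp <- rest[which.min(mean_dur[rest])]
  roles[chirp] <- "short_tonal"
  roles[setdiff(rest, chirp)] <- "long_tonal"
  stats::setNames(roles, cl)
}

#' Assign discrete and graded call types
#'
#' Applies the voiced-percentage boundaries to the clustered calls:
#' long-tonal cluster with voiced percentage >= 95 -> scream; noisy cluster
#' with voiced percentage 0 -> screech; long-tonal below 95 or noisy above
#' 0 -> screech-scream (the graded type combining tonal and noisy parts);
#' short-tonal cluster -> chirp at any voiced percentage. Assignment is
#' total and deterministic.
#'
#' @param hard_labels integer cluster labels.
#' @param cluster_roles named role map from [identify_cluster_roles()] (or a
#'   manual override).
#' @param voiced_percentage per-call voiced percentages.
#' @param tonal_threshold the discrete-tonal boundary (default 95).
#' @return tibble with `cluster`, `role`, `voiced_percentage`, `call_type`.
#' @export
assign_call_types <- function(hard_labels, cluster_roles, voiced_percentage,
                              tonal_threshold = 95) {
  roles <- cluster_roles[as.character(hard_labels)]
  if (any(is.na(roles))) {
    stop("unmapped cluster index: ",
         paste(unique(hard_labels[is.na(roles)]), collapse = ", "))
  }
  vp <- voiced_percentage
  type <- character(length(roles))
  type[roles == "short_tonal"] <- "chirp"
  lt <- roles == "long_tonal"
  type[lt] <- ifelse(vp[lt] >= tonal_threshold, "scream", "screech_scream")
  ns <- roles == "noisy"
  type[ns] <- ifelse(vp[ns] <= 0, "screech", "screech_scream")
  tibble::tibble(cluster = as.integer(hard_labels),
                 role = unname(roles),
                 voiced_percentage = vp,
                 call_type = factor(type, levels = CALL_TYPES))
}
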