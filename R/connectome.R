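#' Desikan-Killiany region labels
#'
#' The 68 cortical region labels of the Desikan-Killiany parcellation in the
#' conventional order: regions 1-34 are the left hemisphere ("LH." prefix),
#' 35-68 the right hemisphere ("RH." prefix), each hemisphere in the same
#' 34-region sequence.
#'
#' @return Character vector of length 68.
#' @export
dk_region_labels <- function() {
  base <- c("BK", "CAC", "CMF", "CU", "EN", "FU", "IP", "IT", "IST", "LO",
            "LOF", "LG", "MOF", "MT", "PH", "PAC", "POP", "POR", "PTR",
            "PCL", "POC", "PCG", "PRC", "PCU", "RAC", "RMF", "SF", "SP",
            "ST", "SMG", "FP", "TP", "TT", "IN")
  c(paste0("LH.", base), paste0("RH.", base))
}

default_labels <- function(n) {
  if (n == 68L) return(dk_region_labels())
  if (n %% 2L == 0L) {
    half <- n %/% 2L
    return(c(sprintf("LH.R%02d", seq_len(half)),
             sprintf("RH.R%02d", seq_len(half))))
  }
  sprintf("R%03d", seq_len(n))
}

#' Structural connectome matrix
#'
#' Wraps an N x N nonnegative symmetric matrix of relative coupling
#' strengths (max-normalized fiber counts: entries in [0, 1], maximum equal
#' to 1 when any connection exists, zero diagonal) together with region
#' labels and a hemisphere assignment.
#'
#' @param weights Square numeric matrix of relative coupling strengths.
#' @param labels Region labels; defaults to the Desikan-Killiany labels for
#'   68 regions, generated labels otherwise.
#' @param hemisphere Optional factor/character vector ("L"/"R") per region;
#'   inferred from an even region count (first half left) when missing.
#' @param normalize If `TRUE`, divide by the global maximum so that the
#'   largest weight is 1 (the convention for fiber-count matrices).
#'
#' @return Object of class `connectome` with elements `weights`, `labels`,
#'   `hemisphere`.
#' @export
connectome <- function(weights, labels = NULL, hemisphere = NULL,
                       normalize = FALSE) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) {
    stop("connectome weights must be square", call. = FALSE)
  }
  if (any(!is.finite(weights))) {
    stop("connectome weights must be finite", call. = FALSE)
  }
  if (any(weights < 0)) {
    stop("connectome weights must be nonnegative", call. = FALSE)
  }
  if (max(abs(weights - t(weights))) > 1e-12) {
    stop("connectome weights must be symmetric", call. = FALSE)
  }
  diag(weights) <- 0
  if (normalize && max(weights) > 0) {
    weights <- weights / max(weights)
  }
  if (max(weights) > 1 + 1e-12) {
    stop("connectome weights must lie in [0, 1]; use normalize = TRUE",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- default_labels(n)
  if (length(labels) != n) {
    stop("length(labels) must equal the number of regions", call. = FALSE)
  }
  if (is.null(hemisphere)) {
    hemisphere <- if (n %% 2L == 0L) {
      rep(c("L", "R"), each = n %/% 2L)
    } else {
      rep(NA_character_, n)
    }
  }
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels,
                 hemisphere = hemisphere),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf("Structural connectome: %d regions\n", nrow(x$weights)))
  cat(sprintf("  density: %.3f, max weight: %g, mean nonzero weight: %.4f\n",
              mean(w > 0), max(x$weights),
              if (any(w > 0)) mean(w[w > 0]) else 0))
  invisible(x)
}

#' @export
dim.connectome <- function(x) dim(x$weights)

n_regions <- function(x) nrow(x$weights)

#' Coupled whole-brain system
#'
#' Binds one shared set of node parameters, a structural connectome and a
#' global coupling coefficient into the coupled system whose effective
#' region-to-region coupling is `c_global * weights[i, j]`.
#'
#' @param params A [wendling_params()] object shared by all regions.
#' @param connectome A [connectome()] object.
#' @param c_global Global coupling coefficient (dimensionless, >= 0) that
#'   rescales all structural weights.
#'
#' @return Object of class `coupled_system`.
#' @export
coupled_system <- function(params = wendling_params(), connectome,
                           c_global = 0) {
  if (!is_wendling_params(params)) {
    stop("params must be a wendling_params object", call. = FALSE)
  }
  if (!inherits(connectome, "connectome")) {
    stop("connectome must be a connectome object", call. = FALSE)
  }
  if (!is.finite(c_global) || c_global < 0) {
    stop("c_global must be finite and >= 0", call. = FALSE)
  }
  structure(list(params = params, connectome = connectome,
                 c_global = c_global),
            class = "coupled_system")
}

#' @export
print.coupled_system <- function(x, ...) {
  cat(sprintf("Coupled Wendling system: %d regions, c_global = %g\n",
              n_regions(x$connectome), x$c_global))
  invisible(x)
}
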