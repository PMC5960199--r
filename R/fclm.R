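#' Enumerate quartets from a four-group hypothesis
#'
#' The quartet set of a four-cluster likelihood-mapping hypothesis is the
#' Cartesian product of the four groups: one taxon drawn from each. With
#' `max_quartets` set, a uniform random subsample without replacement is
#' taken under `seed`; the order is deterministic either way.
#'
#' @param groups a `taxon_groups` with purpose `"fclm_hypothesis"`.
#' @param max_quartets optional cap on the number of quartets.
#' @param seed RNG seed for the subsample (required when subsampling).
#' @return tibble with columns `taxon1` .. `taxon4` (group order).
#' @export
enumerate_quartets <- function(groups, max_quartets = NULL, seed = NULL) {
  if (!inherits(groups, "taxon_groups") || groups$purpose != "fclm_hypothesis") {
    stop("groups must be a taxon_groups with purpose 'fclm_hypothesis'")
  }
  g <- groups$groups
  grid <- expand.grid(taxon4 = g[[4L]], taxon3 = g[[3L]],
                      taxon2 = g[[2L]], taxon1 = g[[1L]],
                      stringsAsFactors = FALSE)[, 4:1]
  out <- tibble::as_tibble(grid)
  if (!is.null(max_quartets) && max_quartets < nrow(out)) {
    idx <- with_seed(seed, sort(sample.int(nrow(out), max_quartets)))
    out <- out[idx, ]
  }
  out
}

#' Simplex coordinates of topology weights
#'
#' Embeds weight vectors in the equilateral triangle with vertices
#' v1 = (0,0), v2 = (1,0), v3 = (0.5, sqrt(3)/2); corner i attracts points
#' supporting topology Ti.
#'
#' @param weights numeric length-3 vector, or an n x 3 matrix of rows on
#'   the simplex.
#' @return n x 2 matrix of xy coordinates.
#' @export
simplex_xy <- function(weights) {
  w <- if (is.matrix(weights)) weights else matrix(weights, nrow = 1L)
  v <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  w %*% v
}

#' Classify a weight vector into the seven likelihood-mapping regions
#'
#' Corner `Ci` when p_i > `corner`; otherwise edge `Eij` (i, j the two
#' largest weights) when the smallest weight is below `edge`; otherwise
#' `center`. Ties break toward the lower region index. The boundary
#' constants approximate the canonical seven-area likelihood-mapping
#' partition and are configurable.
#'
#' @param weights length-3 weight vector or n x 3 matrix.
#' @param corner corner threshold (default 2/3).
#' @param edge edge threshold on the minimum weight (default 1/6).
#' @return character vector of region labels in
#'   `{C1, C2, C3, E12, E13, E23, center}`.
#' @export
classify_region <- function(weights, corner = 2 / 3, edge = 1 / 6) {
  w <- if (is.matrix(weights)) weights else matrix(weights, nrow = 1L)
  apply(w, 1L, function(p) {
    top <- which(p > corner)
    if (length(top)) return(paste0("C", min(top)))
    if (min(p) < edge) {
      big <- sort(order(-p, seq_along(p))[1:2])
      return(paste0("E", big[1L], big[2L]))
    }
    "center"
  })
}

FCLM_REGIONS <- c("C1", "C2", "C3", "E12", "E13", "E23", "center")

#' Four-cluster likelihood mapping
#'
#' For every quartet drawing one taxon from each of the four hypothesis
#' groups: slice the supermatrix, drop columns missing in any quartet
#' member (partition-wise), optimize branch lengths under the three
#' resolved topologies, convert log-likelihoods to simplex weights, and
#' classify the point into the seven regions. Quartets with zero usable
#' sites are counted as undetermined and excluded from proportions.
#'
#' @param supermatrix a `phylo_alignment`.
#' @param groups a `taxon_groups` with purpose `"fclm_hypothesis"`; all
#'   taxa must occur in `supermatrix`.
#' @param scheme optional `partition_scheme` (default: one partition).
#' @param models a `substitution_model` or per-partition list; `NULL`
#'   estimates per-partition models with [estimate_partition_models()].
#' @param max_quartets optional quartet subsample size.
#' @param seed RNG seed for subsampling (and model estimation).
#' @param matrix_label label recorded in the report (e.g. `"original"`,
#'   `"scheme_I"`).
#' @param hypothesis hypothesis name recorded in the report.
#' @param corner,edge region boundary constants, see [classify_region()].
#' @param ... passed to [optimize_quartet()].
#' @return an `fclm_report`: list with `hypothesis`, `matrix_label`,
#'   `n_quartets_total`, `n_undetermined`, `quartets` (per-quartet tibble
#'   with weights, xy, region), `regions` (counts and proportions per
#'   region over determined quartets).
#' @export
run_fclm <- function(supermatrix, groups, scheme = NULL, models = NULL,
                     max_quartets = NULL, seed = NULL,
                     matrix_label = "original", hypothesis = "hypothesis",
                     corner = 2 / 3, edge = 1 / 6, ...) {
  validate_groups_in_alignment(groups, supermatrix)
  if (is.null(scheme)) scheme <- single_partition(supermatrix)
  if (is.null(models)) {
    models <- estimate_partition_models(supermatrix, scheme, seed = seed)
  }
  quartets <- enumerate_quartets(groups, max_quartets = max_quartets,
                                 seed = seed)
  rows <- lapply(seq_len(nrow(quartets)), function(i) {
    taxa <- unlist(quartets[i, ], use.names = FALSE)
    qaln <- slice_alignment(supermatrix, taxa)
    evaluate_quartet(qaln, models, scheme = scheme, ...)
  })
  qt <- dplyr::bind_rows(rows)
  det <- !is.na(qt$p1)
  qt$region <- NA_character_
  if (any(det)) {
    w <- as.matrix(qt[det, c("p1", "p2", "p3")])
    xy <- simplex_xy(w)
    qt$x <- NA_real_; qt$y <- NA_real_
    qt$x[det] <- xy[, 1L]; qt$y[det] <- xy[, 2L]
    qt$region[det] <- classify_region(w, corner = corner, edge = edge)
  } else {
    qt$x <- NA_real_; qt$y <- NA_real_
  }
  counts <- table(factor(qt$region, levels = FCLM_REGIONS))
  regions <- tibble::tibble(
    region = FCLM_REGIONS,
    count = as.integer(counts),
    proportion = if (sum(det)) as.integer(counts) / sum(det) else NA_real_
  )
  structure(list(
    hypothesis = hypothesis, matrix_label = matrix_label,
    group_names = names(groups$groups),
    n_quartets_total = nrow(qt), n_undetermined = sum(!det),
    quartets = qt, regions = regions,
    corner = corner, edge = edge
  ), class = "fclm_report")
}

#' @export
print.fclm_report <- function(x, ...) {
  cat(sprintf("<fclm_report> %s on %s: %d quartets (%d undetermined)\n",
              x$hypothesis, x$matrix_label, x$n_quartets_total,
              x$n_undetermined))
  props <- stats::setNames(x$regions$proportion, x$regions$region)
  cat(paste(sprintf("%s=%.3f", names(props), props), collapse = "  "), "\n")
  invisible(x)
}

#' @export
tidy.fclm_report <- function(x, ...) {
  x$quartets
}

#' @export
glance.fclm_report <- function(x, ...) {
  wide <- stats::setNames(as.list(x$regions$proportion),
                          paste0("prop_", x$regions$region))
  tibble::as_tibble(c(list(hypothesis = x$hypothesis,
                           matrix_label = x$matrix_label,
                           n_quartets_total = x$n_quartets_total,
                           n_undetermined = x$n_undetermined), wide))
}

#' Simplex scatter plot of an FcLM report
#'
#' Draws determined quartets in the equilateral-triangle embedding, with
#' the seven-region boundaries at the report's corner/edge constants.
#'
#' @param object an `fclm_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fclm_report <- function(object, ...) {
  tri <- as.data.frame(simplex_xy(diag(3)))
  names(tri) <- c("x", "y")
  tri <- rbind(tri, tri[1L, ])
  # region boundary segments: corner cut-offs p_i = corner and the inner
  # edge/center frontier p_min = edge, each a straight chord of the triangle
  chord <- function(fix_i, value) {
    pts <- list()
    others <- setdiff(1:3, fix_i)
    for (j in others) {
      p <- numeric(3L)
      p[fix_i] <- value
      p[j] <- 1 - value
      pts[[length(pts) + 1L]] <- p
    }
    xy <- simplex_xy(do.call(rbind, pts))
    data.frame(x = xy[1L, 1L], y = xy[1L, 2L], xend = xy[2L, 1L],
               yend = xy[2L, 2L])
  }
  segs <- dplyr::bind_rows(
    lapply(1:3, chord, value = object$corner),
    lapply(1:3, chord, value = object$edge)
  )
  pts <- object$quartets[!is.na(object$quartets$region), ]
  lab <- simplex_xy(diag(3)) * 1.08 - 0.04
  labels <- data.frame(x = lab[, 1L], y = lab[, 2L],
                       text = object$group_names[c(2L, 3L, 4L)])
  ggplot2::ggplot() +
    ggplot2::geom_path(data = tri, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          linetype = "dashed", color = "grey50") +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        alpha = 0.5, size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("FcLM: %s (%s)", object$hypothesis,
                                  object$matrix_label),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Permutation-corrected region support
#'
#' Compares an FcLM report on the original matrix with one on a permuted
#' null matrix from the same hypothesis and quartet sample:
#' corrected_i = max(0, original_i - permuted_i) per region. The dominant
#' corner before and after correction is reported alongside.
#'
#' @param original,permuted `fclm_report`s with equal hypothesis and
#'   quartet totals.
#' @return tibble of class `fclm_correction` with columns `region`,
#'   `original`, `permuted`, `corrected`; attributes `argmax_before`,
#'   `argmax_after` give the dominant corner region.
#' @export
corrected_support <- function(original, permuted) {
  if (!identical(original$hypothesis, permuted$hypothesis)) {
    stop("reports come from different hypotheses: ",
         original$hypothesis, " vs ", permuted$hypothesis)
  }
  if (original$n_quartets_total != permuted$n_quartets_total) {
    stop("reports cover different quartet counts: ",
         original$n_quartets_total, " vs ", permuted$n_quartets_total)
  }
  p_orig <- original$regions$proportion
  p_perm <- permuted$regions$proportion
  out <- tibble::tibble(
    region = original$regions$region,
    original = p_orig,
    permuted = p_perm,
    corrected = pmax(0, p_orig - p_perm)
  )
  corners <- out$region %in% c("C1", "C2", "C3")
  attr(out, "argmax_before") <- out$region[corners][
    which.max(out$original[corners])]
  attr(out, "argmax_after") <- out$region[corners][
    which.max(out$corrected[corners])]
  class(out) <- c("fclm_correction", class(out))
  out
}
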