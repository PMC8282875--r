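# Ordered boundary-pair aggregates of a label map (4-adjacency).
# Returns a data.frame with one row per ordered adjacent label pair (a, b):
# n = number of adjacent pixel pairs, isum = sum of the intensity of the
# a-side pixel over those pairs (NULL intensity -> 0).
boundary_pairs <- function(labels, intensity = NULL) {
  nr <- nrow(labels); nc <- ncol(labels)
  if (is.null(intensity)) intensity <- matrix(0, nr, nc)
  a <- c(labels[-nr, ], labels[, -nc], labels[-1L, ], labels[, -1L])
  b <- c(labels[-1L, ], labels[, -1L], labels[-nr, ], labels[, -nc])
  ia <- c(intensity[-nr, ], intensity[, -nc], intensity[-1L, ], intensity[, -1L])
  keep <- a != b
  a <- a[keep]; b <- b[keep]; ia <- ia[keep]
  if (!length(a))
    return(data.frame(a = integer(0), b = integer(0), n = integer(0),
                      isum = numeric(0)))
  mmax <- max(labels) + 1
  key <- (a - min(labels)) * mmax + (b - min(labels))
  n <- rowsum(rep(1L, length(key)), key)
  isum <- rowsum(ia, key)
  kv <- as.numeric(rownames(n))
  data.frame(a = as.integer(kv %/% mmax) + min(labels),
             b = as.integer(kv %% mmax) + min(labels),
             n = as.vector(n), isum = as.vector(isum))
}

#' Segment enclosure hierarchy
#'
#' Reconstructs the hierarchy of nested contours: a segment is the child of
#' the smallest segment that completely encloses it, where "encloses" means
#' the child lies inside a hole of the enclosing segment (every path from
#' the child to the image border crosses the parent). The immediately
#' enclosing (minimal filled-area) container is recorded as the parent. A
#' segment fully surrounded by a single pixel-adjacent neighbour is the
#' special case of this definition. Segments touching the image border are
#' never children (their surround is open). All segments without a parent
#' form the residual set.
#'
#' @param final_labels integer label matrix (0 = background segment allowed).
#' @return an `msm_hierarchy`: list with `nodes` (all labels), `parent_of`
#'   (named integer vector child -> parent), `residual` (labels without a
#'   parent), `adjacency` (data.frame a/b/n of ordered boundary pairs), and
#'   `border_labels`.
#' @export
build_enclosure_hierarchy <- function(final_labels) {
  labels <- as_label_matrix(final_labels)
  bp <- boundary_pairs(labels)
  nodes <- sort(unique(as.vector(labels)))
  border <- sort(unique(c(labels[1L, ], labels[nrow(labels), ],
                          labels[, 1L], labels[, ncol(labels)])))
  nr <- nrow(labels); nc <- ncol(labels)
  pix <- split(seq_along(labels), as.vector(labels))

  # container of each node: minimal filled area among segments whose holes
  # contain it
  cont_parent <- rep(NA_integer_, length(nodes))
  cont_fill <- rep(Inf, length(nodes))
  names(cont_parent) <- names(cont_fill) <- nodes
  for (a in nodes) {
    p <- pix[[as.character(a)]]
    ri <- (p - 1L) %% nr + 1L
    ci <- (p - 1L) %/% nr + 1L
    r0 <- min(ri); r1 <- max(ri); c0 <- min(ci); c1 <- max(ci)
    h <- r1 - r0 + 1L; w <- c1 - c0 + 1L
    # complement of `a` in its padded bounding box; the pad ring stands for
    # the rest of the image (and beyond), so components touching it are open
    comp <- matrix(TRUE, h + 2L, w + 2L)
    comp[2L:(h + 1L), 2L:(w + 1L)] <- labels[r0:r1, c0:c1, drop = FALSE] != a
    cc <- cc_label_cpp(comp, 4L)
    open_ids <- unique(c(cc[1L, ], cc[h + 2L, ], cc[, 1L], cc[, w + 2L]))
    hole <- comp & !(cc %in% open_ids)
    dim(hole) <- dim(cc)
    if (!any(hole)) next
    hole_in <- hole[2L:(h + 1L), 2L:(w + 1L), drop = FALSE]
    inside <- unique(labels[r0:r1, c0:c1, drop = FALSE][hole_in])
    fill_area <- length(p) + sum(hole_in)
    for (b in inside) {
      key <- as.character(b)
      if (fill_area < cont_fill[key] ||
          (fill_area == cont_fill[key] && a < cont_parent[key])) {
        cont_fill[key] <- fill_area
        cont_parent[key] <- a
      }
    }
  }
  ok <- !is.na(cont_parent) & !(nodes %in% border)
  parent_of <- stats::setNames(as.integer(cont_parent[ok]), nodes[ok])
  residual <- setdiff(nodes, as.integer(names(parent_of)))
  structure(list(nodes = nodes, parent_of = parent_of, residual = residual,
                 adjacency = bp, border_labels = border),
            class = "msm_hierarchy")
}

#' Iterative OCIN labelling
#'
#' Classifies every segment as a potential nucleus or potential cell from the
#' outer-cell/inner-nucleus sign rule: the sum of boundary intensity
#' differences (inner minus outer) is negative for a dark segment inside a
#' brighter surround. Iteration 1 labels all fully enclosed children against
#' their parent. In later iterations a residual segment qualifies when
#' exactly one of its neighbours is still unlabelled; the sign rule is
#' evaluated against that pseudo-parent across their shared boundary.
#' Positive signs become cells; negative signs become nuclei unless two
#' negative-signed qualifying segments are adjacent, in which case they stay
#' residual. The hierarchy index `H` records the labelling iteration. If an
#' iteration assigns nothing while the residual is non-empty, the remaining
#' segments are labelled by the sign of their mean against the area-weighted
#' mean of all their neighbours at the current iteration (logged fallback).
#'
#' @param hierarchy `msm_hierarchy` from [build_enclosure_hierarchy()].
#' @param means per-segment mean intensities, indexed by `label + 1 -
#'   min(label)` in the order of `hierarchy$nodes`; pass a named vector with
#'   names equal to the labels, or an unnamed vector aligned with
#'   `hierarchy$nodes`.
#' @param boundary_mode `"segment-mean"` (default): the sign test compares
#'   segment mean intensities; `"raw-pixel"`: boundary pixel intensities of
#'   the original image are summed (requires `intensity` at build time, see
#'   [semantic_assign()]).
#' @param raw_isum optional precomputed data.frame of ordered boundary-pair
#'   intensity sums (internal use for raw-pixel mode).
#' @param areas per-segment pixel areas (needed for the fallback), aligned
#'   like `means`.
#' @param quiet suppress the fallback message.
#' @return data.frame with `label`, `ocin_class` ("nucleus"/"cell"), `H`.
#' @export
ocin_assign <- function(hierarchy, means, areas = NULL,
                        boundary_mode = c("segment-mean", "raw-pixel"),
                        raw_isum = NULL, quiet = FALSE) {
  boundary_mode <- match.arg(boundary_mode)
  nodes <- hierarchy$nodes
  nn <- length(nodes)
  if (!is.null(names(means))) means <- means[as.character(nodes)]
  if (length(means) != nn) stop("means must align with hierarchy$nodes")
  if (is.null(areas)) areas <- rep(1, nn)
  if (!is.null(names(areas))) areas <- areas[as.character(nodes)]
  idx <- stats::setNames(seq_len(nn), nodes)
  bp <- hierarchy$adjacency
  ai <- idx[as.character(bp$a)]
  bi <- idx[as.character(bp$b)]
  neigh <- split(bi, ai)

  # signed inner-vs-outer evaluation for segment i against counterpart j
  if (boundary_mode == "raw-pixel") {
    if (is.null(raw_isum)) stop("raw-pixel mode requires raw_isum")
    ra <- idx[as.character(raw_isum$a)]
    rb <- idx[as.character(raw_isum$b)]
  }
  pair_sign <- function(i, j) {
    if (boundary_mode == "segment-mean") {
      means[i] - means[j]
    } else {
      sel <- ra == i & rb == j
      if (!any(sel)) return(means[i] - means[j])  # no shared boundary
      sum(raw_isum$isum[sel]) - sum(raw_isum$isum[ra == j & rb == i])
    }
  }

  cls <- rep(NA_character_, nn)
  H <- rep(NA_integer_, nn)

  # iteration 1: fully enclosed children against their true parent. The
  # relation classifies the pair: a darker inner segment is a nucleus and its
  # enclosing brighter segment the outer cell; a brighter inner segment is a
  # cell. Parents of brighter children stay unlabelled (the relation says
  # nothing about a darker surround).
  if (length(hierarchy$parent_of)) {
    ch <- idx[names(hierarchy$parent_of)]
    pa <- idx[as.character(hierarchy$parent_of)]
    for (t in seq_along(ch)) {
      s <- pair_sign(ch[t], pa[t])
      if (s < 0) {
        cls[ch[t]] <- "nucleus"
        if (is.na(cls[pa[t]])) { cls[pa[t]] <- "cell"; H[pa[t]] <- 1L }
      } else {
        cls[ch[t]] <- "cell"
      }
      H[ch[t]] <- 1L
    }
  }

  iter <- 1L
  repeat {
    residual <- which(is.na(cls))
    if (!length(residual)) break
    iter <- iter + 1L
    frozen_unlab <- is.na(cls)  # labels frozen at iteration start
    qual <- integer(0); pseudo <- integer(0)
    for (i in residual) {
      nb <- unique(neigh[[as.character(i)]])
      un <- nb[frozen_unlab[nb]]
      if (length(un) == 1L) {
        qual <- c(qual, i)
        pseudo <- c(pseudo, un)
      }
    }
    assigned <- FALSE
    if (length(qual)) {
      s <- vapply(seq_along(qual),
                  function(t) pair_sign(qual[t], pseudo[t]), numeric(1))
      pos <- qual[s >= 0]
      negs <- qual[s < 0]
      for (i in pos) { cls[i] <- "cell"; H[i] <- iter; assigned <- TRUE }
      if (length(negs)) {
        negset <- negs
        for (i in negs) {
          nb <- unique(neigh[[as.character(i)]])
          if (any(nb %in% negset)) next  # adjacent negatives stay residual
          cls[i] <- "nucleus"; H[i] <- iter; assigned <- TRUE
        }
      }
    }
    if (!assigned) {
      # stalled: label the remaining residual against the area-weighted
      # mean of all neighbours
      if (!quiet)
        message(sprintf(
          "OCIN iteration stalled at step %d; falling back for %d segment(s)",
          iter, length(residual)))
      for (i in residual) {
        nb <- neigh[[as.character(i)]]
        if (is.null(nb) || !length(nb)) {  # isolated segment: call it cell
          cls[i] <- "cell"; H[i] <- iter
          next
        }
        nb <- unique(nb)
        mnb <- sum(means[nb] * areas[nb]) / sum(areas[nb])
        cls[i] <- if (means[i] - mnb < 0) "nucleus" else "cell"
        H[i] <- iter
      }
      break
    }
  }
  data.frame(label = nodes, ocin_class = cls, H = H)
}

#' Crofton-style perimeter estimate
#'
#' Counts chord runs of the mask along the horizontal, vertical, and both
#' diagonal directions and combines them by the Cauchy-Crofton formula
#' `P = pi/4 * (R0 + R90 + (R45 + R135) / sqrt(2))` with `R` the run counts.
#' Unbiased for a disk up to discretization.
#'
#' @param mask logical matrix.
#' @return perimeter estimate in pixels.
#' @export
crofton_perimeter <- function(mask) {
  v <- mask * 1L
  nr <- nrow(v); nc <- ncol(v)
  runs <- function(prev) sum(v == 1L & prev == 0L)
  p_left <- cbind(0L, v[, -nc, drop = FALSE])
  p_up <- rbind(0L, v[-nr, , drop = FALSE])
  p_ul <- matrix(0L, nr, nc)
  if (nr > 1L && nc > 1L)
    p_ul[2:nr, 2:nc] <- v[1:(nr - 1L), 1:(nc - 1L)]
  p_ur <- matrix(0L, nr, nc)
  if (nr > 1L && nc > 1L)
    p_ur[2:nr, 1:(nc - 1L)] <- v[1:(nr - 1L), 2:nc]
  r0 <- runs(p_left); r90 <- runs(p_up)
  r45 <- runs(p_ul); r135 <- runs(p_ur)
  pi / 4 * (r0 + r90 + (r45 + r135) / sqrt(2))
}

# Pixel-count perimeter: number of mask pixels with a 4-neighbour outside
# the mask (matrix border counts as outside).
pixelcount_perimeter <- function(mask) {
  v <- mask * 1L
  nr <- nrow(v); nc <- ncol(v)
  out <- cbind(0L, v[, -nc, drop = FALSE]) == 0L |
         cbind(v[, -1L, drop = FALSE], 0L) == 0L |
         rbind(0L, v[-nr, , drop = FALSE]) == 0L |
         rbind(v[-1L, , drop = FALSE], 0L) == 0L
  sum(mask & out)
}

#' Compactness of a segment
#'
#' `C = P^2 / (4 * pi * A)` with `P` an estimated perimeter and `A` the pixel
#' area; 1 for a circle, larger for elongated or ragged shapes.
#'
#' @param segment_mask non-empty logical matrix.
#' @param perimeter `"crofton"` (default, low-bias for disks) or
#'   `"pixel-count"` (boundary-pixel count; biased high).
#' @return compactness value (>= ~1 up to discretization for connected masks).
#' @export
compactness <- function(segment_mask, perimeter = c("crofton", "pixel-count")) {
  perimeter <- match.arg(perimeter)
  if (!is.logical(segment_mask)) storage.mode(segment_mask) <- "logical"
  A <- sum(segment_mask)
  if (A == 0) stop("segment mask is empty")
  P <- switch(perimeter,
              "crofton" = crofton_perimeter(segment_mask),
              "pixel-count" = pixelcount_perimeter(segment_mask))
  compactness_from_PA(P, A)
}

#' @rdname compactness
#' @param P perimeter.
#' @param A area.
#' @export
compactness_from_PA <- function(P, A) P^2 / (4 * pi * A)

#' Mean gradient magnitude along a segment contour
#'
#' Mean, over the inner-contour pixels of the mask (mask pixels with at
#' least one 4-neighbour outside the mask within the image), of the
#' central-difference gradient magnitude of `img` (reflected borders).
#'
#' @param segment_mask non-empty logical matrix.
#' @param img numeric matrix of the same shape.
#' @return non-negative scalar.
#' @export
contour_gradient <- function(segment_mask, img) {
  if (!all(dim(segment_mask) == dim(img))) stop("shape mismatch")
  if (!any(segment_mask)) stop("segment mask is empty")
  gm <- central_gradient_magnitude(as_matrix(img))
  contour <- inner_contour(segment_mask)
  mean(gm[contour])
}

central_gradient_magnitude <- function(m) {
  gx <- (shift_reflect(m, 0L, 1L) - shift_reflect(m, 0L, -1L)) / 2
  gy <- (shift_reflect(m, 1L, 0L) - shift_reflect(m, -1L, 0L)) / 2
  sqrt(gx^2 + gy^2)
}

# Inner contour: mask pixels with >= 1 in-image 4-neighbour outside the mask.
inner_contour <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  v <- mask * 1L
  nb_out <- cbind(1L, v[, -nc, drop = FALSE]) == 0L & col(v) > 1L
  nb_out <- nb_out | (cbind(v[, -1L, drop = FALSE], 1L) == 0L & col(v) < nc)
  nb_out <- nb_out | (rbind(1L, v[-nr, , drop = FALSE]) == 0L & row(v) > 1L)
  nb_out <- nb_out | (rbind(v[-1L, , drop = FALSE], 1L) == 0L & row(v) < nr)
  mask & nb_out
}

#' Nucleus quality scores
#'
#' Euclidean distance of the normalized feature vector (stability, contour
#' gradient, compactness, OCIN hierarchy index) from the all-ones reference.
#' Components: `S / MSM_max`, `|grad| / I_max`, `(C_max + 1 - C) / C_max`,
#' `(OCIN_max + 1 - H) / OCIN_max`, with `C_max` and `OCIN_max` the scene
#' maxima over the scored candidates. Only OCIN nucleus candidates are
#' scored; `d = 0` corresponds to the ideal nucleus model.
#'
#' @param features data.frame with columns `label`, `S`, `grad`, `C`, `H`
#'   (nucleus candidates only).
#' @param MSM_max number of merge thresholds (default 7).
#' @param I_max intensity maximum of the data type (default 255).
#' @return `features` with columns `d` appended.
#' @export
quality_scores <- function(features, MSM_max = 7, I_max = 255) {
  if (!all(c("label", "S", "grad", "C", "H") %in% names(features)))
    stop("features must have columns label, S, grad, C, H")
  if (!is.finite(MSM_max) || MSM_max <= 0) stop("MSM_max must be > 0")
  if (!is.finite(I_max) || I_max <= 0) stop("I_max must be > 0")
  if (!nrow(features)) {
    features$d <- numeric(0)
    return(features)
  }
  C_max <- max(features$C)
  OCIN_max <- max(features$H)
  v1 <- features$S / MSM_max
  v2 <- features$grad / I_max
  v3 <- (C_max + 1 - features$C) / C_max
  v4 <- (OCIN_max + 1 - features$H) / OCIN_max
  features$d <- sqrt((v1 - 1)^2 + (v2 - 1)^2 + (v3 - 1)^2 + (v4 - 1)^2)
  features
}

#' Select nuclei by the relative quality threshold
#'
#' A candidate is selected iff `d < (max(d) - min(d)) * (1 - T_qual) +
#' min(d)` (strict inequality). `T_qual = 1` therefore selects nothing and
#' `T_qual = 0` selects everything except the worst-scoring ties.
#'
#' @param scores data.frame with columns `label` and `d`.
#' @param T_qual relative quality threshold in \[0, 1\].
#' @return integer vector of selected labels (possibly empty).
#' @export
select_nuclei <- function(scores, T_qual = 0.97) {
  if (!is.finite(T_qual) || T_qual < 0 || T_qual > 1)
    stop("T_qual must lie in [0, 1]")
  if (!nrow(scores)) return(integer(0))
  d <- scores$d
  thr <- (max(d) - min(d)) * (1 - T_qual) + min(d)
  scores$label[d < thr]
}

#' Final nucleus / cytoplasm / matrix classification
#'
#' Selected segments become nuclei; segments that are OCIN cell candidates
#' and 4-adjacent to at least one selected nucleus become cytoplasm; all
#' remaining pixels (including the residual background segment) are
#' intercellular matrix.
#'
#' @param final_labels label matrix (0 = background).
#' @param selected labels selected by [select_nuclei()].
#' @param adjacency ordered boundary-pair data.frame (columns `a`, `b`).
#' @param ocin data.frame from [ocin_assign()].
#' @return list with `class_map` (integer matrix: 0 matrix, 1 cytoplasm,
#'   2 nucleus) and `cytoplasm_of` (named list nucleus label -> adjacent
#'   cytoplasm labels).
#' @export
assign_classes <- function(final_labels, selected, adjacency, ocin) {
  lmax <- max(final_labels)
  cls_vec <- integer(lmax + 1L)  # index = label + 1
  cyto_of <- list()
  if (length(selected)) {
    cls_vec[selected + 1L] <- 2L
    cellset <- ocin$label[ocin$ocin_class == "cell"]
    for (nuc in selected) {
      nb <- adjacency$b[adjacency$a == nuc]
      cyt <- intersect(nb, cellset)
      cyt <- setdiff(cyt, c(0L, selected))  # background stays matrix
      if (length(cyt)) cls_vec[cyt + 1L] <- pmax(cls_vec[cyt + 1L], 1L)
      cyto_of[[as.character(nuc)]] <- cyt
    }
  }
  class_map <- matrix(cls_vec[final_labels + 1L],
                      nrow(final_labels), ncol(final_labels))
  list(class_map = class_map, cytoplasm_of = cyto_of)
}

#' Semantic assignment driver
#'
#' Builds the enclosure hierarchy of the multi-stage segment map, assigns
#' OCIN classes iteratively, computes the four nucleus features for every
#' OCIN nucleus candidate (stability, contour gradient on the diffused
#' image, compactness, hierarchy index), scores them, applies the relative
#' quality threshold, and emits the final classification.
#'
#' @param msr `msm_multistage` result from [multistage_merge()].
#' @param intensity intensity image for gradients and raw boundary sums
#'   (typically the diffused image).
#' @param T_qual relative quality threshold (default 0.97).
#' @param boundary_mode OCIN sign test mode, see [ocin_assign()].
#' @param perimeter perimeter estimator, see [compactness()].
#' @param I_max intensity normalizer for the gradient feature (default 255).
#' @param quiet suppress OCIN fallback messages.
#' @return list with `features` (all candidates with `d` and `selected`),
#'   `ocin` (all segments), `hierarchy`, `class_map`, `cytoplasm_of`,
#'   `selected`.
#' @export
semantic_assign <- function(msr, intensity, T_qual = 0.97,
                            boundary_mode = c("segment-mean", "raw-pixel"),
                            perimeter = c("crofton", "pixel-count"),
                            I_max = 255, quiet = FALSE) {
  boundary_mode <- match.arg(boundary_mode)
  perimeter <- match.arg(perimeter)
  labels <- msr$final_labels
  hier <- build_enclosure_hierarchy(labels)
  raw_isum <- NULL
  if (boundary_mode == "raw-pixel")
    raw_isum <- boundary_pairs(labels, as_matrix(intensity))
  means <- stats::setNames(msr$seg_mean[hier$nodes + 1L], hier$nodes)
  areas <- stats::setNames(msr$seg_area[hier$nodes + 1L], hier$nodes)
  ocin <- ocin_assign(hier, means, areas, boundary_mode, raw_isum,
                      quiet = quiet)

  cand <- ocin$label[ocin$ocin_class == "nucleus" & ocin$label != 0L]
  feats <- data.frame(label = integer(0), area = numeric(0), mean = numeric(0),
                      S = numeric(0), grad = numeric(0), C = numeric(0),
                      H = integer(0))
  if (length(cand)) {
    gm <- central_gradient_magnitude(as_matrix(intensity))
    contour <- inner_contour_labels(labels)
    csum <- rowsum(gm[contour], labels[contour])
    ccnt <- rowsum(rep(1, sum(contour)), labels[contour])
    gmean <- stats::setNames(as.vector(csum) / as.vector(ccnt),
                             rownames(csum))
    Cv <- vapply(cand, function(l) {
      compactness(crop_mask(labels, l), perimeter)
    }, numeric(1))
    Hv <- ocin$H[match(cand, ocin$label)]
    feats <- data.frame(
      label = cand,
      area = as.numeric(areas[as.character(cand)]),
      mean = as.numeric(means[as.character(cand)]),
      S = msr$stability_seg[cand + 1L],
      grad = as.numeric(gmean[as.character(cand)]),
      C = Cv,
      H = Hv)
  }
  feats <- quality_scores(feats, MSM_max = msr$msm_max, I_max = I_max)
  selected <- select_nuclei(feats, T_qual)
  feats$selected <- feats$label %in% selected
  cl <- assign_classes(labels, selected, hier$adjacency, ocin)
  list(features = feats, ocin = ocin, hierarchy = hier,
       class_map = cl$class_map, cytoplasm_of = cl$cytoplasm_of,
       selected = selected, T_qual = T_qual)
}

# Contour pixels of every segment at once: label differs from some in-image
# 4-neighbour.
inner_contour_labels <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  d <- matrix(FALSE, nr, nc)
  d[, -1L] <- d[, -1L] | labels[, -1L] != labels[, -nc]
  d[, -nc] <- d[, -nc] | labels[, -nc] != labels[, -1L]
  d[-1L, ] <- d[-1L, ] | labels[-1L, ] != labels[-nr, ]
  d[-nr, ] <- d[-nr, ] | labels[-nr, ] != labels[-1L, ]
  d
}

# Cropped bounding-box mask of one label (fast per-segment shape analysis).
crop_mask <- function(labels, l) {
  w <- which(labels == l, arr.ind = TRUE)
  r <- range(w[, 1L]); c <- range(w[, 2L])
  labels[r[1L]:r[2L], c[1L]:c[2L], drop = FALSE] == l
}
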