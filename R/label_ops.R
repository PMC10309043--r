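# Ground-truth class mapping and conversions: filled-in instance
# segmentations to membrane (contour) ground truth, and membrane masks to
# 1-pixel-wide skeletons. Masks and skeletons use 8-connectivity
# throughout; the structuring element is the Euclidean disk
# {(di, dj): di^2 + dj^2 <= r^2}.

#' Class scheme for semantic segmentation labels
#'
#' Two classes (intracellular, membrane) or three (plus "other", e.g.
#' extracellular space or tissue exterior to the specimen). Class indices
#' are contiguous: intracellular = 0, membrane = 1, other = 2; unlabeled
#' pixels carry the sentinel.
#'
#' @param n_classes 2 or 3.
#' @param map optional named integer vector mapping raw label ids (names)
#'   to class indices, used by [map_classes()].
#' @param unlabeled sentinel id for unannotated pixels.
#' @return A `class_scheme` object.
#' @export
class_scheme <- function(n_classes = 3L, map = NULL, unlabeled = EMSEG_UNLABELED) {
  if (!n_classes %in% c(2L, 3L)) stopf("n_classes must be 2 or 3")
  classes <- c(intracellular = 0L, membrane = 1L, other = 2L)[seq_len(n_classes)]
  if (!is.null(map)) {
    if (is.null(names(map))) stopf("`map` must be a named vector (raw id -> class index)")
    if (any(!map %in% c(classes, unlabeled)))
      stopf("`map` targets must be class indices of the scheme (or the unlabeled sentinel)")
  }
  structure(list(n_classes = as.integer(n_classes), classes = classes,
                 map = map, unlabeled = as.integer(unlabeled)),
            class = "class_scheme")
}

#' Membrane-conversion parameters
#'
#' @param radius erosion/dilation filter radius in pixels (>= 1). Each
#'   instance is eroded by this depth, so the membrane band between two
#'   abutting instances is `2 * radius` wide.
#' @param fill_ecs treat extracellular space as membrane: with 2 classes
#'   all background becomes membrane; with 3 classes only background
#'   within `radius` of two or more distinct instances does.
#' @return A `membrane_params` object.
#' @export
membrane_params <- function(radius = 1L, fill_ecs = TRUE) {
  radius <- check_count(radius, "radius")
  check_flag(fill_ecs, "fill_ecs")
  structure(list(radius = radius, fill_ecs = fill_ecs), class = "membrane_params")
}

#' Convert a filled-in instance segmentation to membrane ground truth
#'
#' Each instance (ids >= 1; 0 is background/extracellular space) is eroded
#' by a disk of the configured radius; the pixels the erosion removes
#' become membrane class, the remaining interior stays intracellular.
#' Background handling follows `fill_ecs` (see [membrane_params()]); with
#' 3 classes, background not turned into membrane becomes "other", and
#' with 2 classes and `fill_ecs = FALSE` it is left unlabeled. The output
#' classes partition the image. An instance entirely consumed by the
#' erosion becomes pure membrane, with a warning.
#'
#' @param instances integer instance-id matrix.
#' @param params a [membrane_params()].
#' @param scheme a [class_scheme()].
#' @return Integer class-index matrix.
#' @export
instance_to_membrane <- function(instances, params = membrane_params(),
                                 scheme = class_scheme(3L)) {
  if (any(instances < 0L)) stopf("instance ids must be >= 0 (0 = background)")
  r <- params$radius
  ids <- sort(unique(instances[instances > 0L]))
  h <- nrow(instances); w <- ncol(instances)
  membrane <- matrix(FALSE, h, w)
  interior <- matrix(FALSE, h, w)
  near_count <- if (params$fill_ecs && scheme$n_classes == 3L) matrix(0L, h, w) else NULL
  for (id in ids) {
    m <- instances == id
    e <- cpp_erode_disk(m, r)
    if (!any(e))
      warning(sprintf("instance %d vanished under erosion radius %d; it is pure membrane", id, r),
              call. = FALSE)
    membrane <- membrane | (m & !e)
    interior <- interior | e
    if (!is.null(near_count)) near_count <- near_count + cpp_dilate_disk(m, r)
  }
  background <- instances == 0L
  out <- matrix(scheme$unlabeled, h, w)
  out[interior] <- scheme$classes[["intracellular"]]
  out[membrane] <- scheme$classes[["membrane"]]
  if (params$fill_ecs) {
    if (scheme$n_classes == 2L) {
      out[background] <- scheme$classes[["membrane"]]
    } else {
      touch2 <- background & near_count >= 2L
      out[touch2] <- scheme$classes[["membrane"]]
      out[background & !touch2] <- scheme$classes[["other"]]
    }
  } else if (scheme$n_classes == 3L) {
    out[background] <- scheme$classes[["other"]]
  }
  # 2-class without ECS fill leaves background unlabeled (sentinel)
  matrix(as.integer(out), h, w)
}

#' Thin a membrane mask to a 1-pixel-wide skeleton
#'
#' Morphological (Guo-Hall) thinning toward the medial axis of the
#' membrane network: the skeleton is a subset of the mask, at most one
#' pixel wide, and preserves the mask's 8-connected component structure.
#' Training on such skeletons teaches networks the neuronal backbone,
#' which downstream agglomeration methods can exploit.
#'
#' @param membrane logical (or 0/1) membrane mask.
#' @return Logical skeleton mask of the same shape.
#' @export
membrane_to_skeleton <- function(membrane) {
  m <- membrane != 0
  storage.mode(m) <- "logical"
  cpp_thin_guo_hall(m)
}

#' Relabel an image onto a class scheme
#'
#' Surjectively maps raw label ids onto the scheme's contiguous class
#' indices using `scheme$map`; the unlabeled sentinel is preserved as-is.
#' Ids without a mapping raise an error listing them.
#'
#' @param labels integer label matrix.
#' @param scheme a [class_scheme()] with a `map`.
#' @return Integer class-index matrix.
#' @export
map_classes <- function(labels, scheme) {
  if (is.null(scheme$map)) stopf("scheme has no id -> class map")
  ids <- unique(as.vector(labels))
  ids <- ids[ids != scheme$unlabeled]
  unmapped <- setdiff(as.character(ids), names(scheme$map))
  if (length(unmapped) > 0L)
    stopf("label id(s) not covered by the class scheme: %s",
          paste(unmapped, collapse = ", "))
  out <- labels
  sel <- labels != scheme$unlabeled
  out[sel] <- scheme$map[as.character(labels[sel])]
  matrix(as.integer(out), nrow(labels), ncol(labels))
}
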