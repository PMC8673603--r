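#' Facet catalog: wear-facet label to power-stroke phase class
#'
#' Wear facets are labelled on the occlusal surface and grouped by the phase
#' of the power stroke that forms them: buccal phase I (`BPI`), lingual phase
#' I (`LPI`), phase II (`PII`), or tip-crush areas (`TIP_CRUSH`, produced by
#' puncture-crushing and excluded from the phase composition).
#'
#' @param mapping named character vector or list: facet label -> phase class.
#' @return object of class `facet_catalog` (named character vector).
#' @export
facet_catalog <- function(mapping) {
  m <- unlist(mapping)
  classes <- c("BPI", "LPI", "PII", "TIP_CRUSH")
  if (is.null(names(m)) || any(!nzchar(names(m))))
    stop("facet catalog mapping must be named by facet label", call. = FALSE)
  if (any(duplicated(names(m))))
    stop("duplicate facet labels in catalog", call. = FALSE)
  bad <- setdiff(unique(m), classes)
  if (length(bad) > 0L)
    stop("unknown phase class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(stats::setNames(as.character(m), names(m)), class = "facet_catalog")
}

#' Default facet catalog
#'
#' Facet numbering after the conventional molar wear-facet scheme: labels
#' 1-4 are buccal phase I, 5-8 lingual phase I, 9-13 phase II, plus four
#' named cusp-tip crush areas. Shipped as a JSON data file and overridable
#' per project with [read_facet_catalog()].
#'
#' @return a [facet_catalog()].
#' @export
default_facet_catalog <- function() {
  read_facet_catalog(system.file("extdata", "facet_catalog_default.json",
                                 package = "molarwear", mustWork = TRUE))
}

#' Read / write a facet catalog as JSON (`{"label": "CLASS", ...}`)
#' @param path JSON file path.
#' @return a [facet_catalog()].
#' @export
read_facet_catalog <- function(path) {
  facet_catalog(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_facet_catalog
#' @param catalog a [facet_catalog()].
#' @export
write_facet_catalog <- function(catalog, path) {
  jsonlite::write_json(as.list(unclass(catalog)), path, auto_unbox = TRUE)
  invisible(path)
}

#' Per-face facet annotation
#'
#' Maps mesh faces to facet labels; unlabeled faces carry no wear facet.
#' The CSV interface uses 0-based face indices (`face_index,facet_label`);
#' in-memory indices are 1-based.
#'
#' @param face_index integer vector of 1-based face indices.
#' @param facet_label character vector of labels, same length.
#' @return object of class `facet_annotation` (data.frame).
#' @export
facet_annotation <- function(face_index, facet_label) {
  face_index <- as.integer(face_index)
  facet_label <- as.character(facet_label)
  stopifnot(length(face_index) == length(facet_label))
  if (anyDuplicated(face_index))
    stop("a face may carry at most one facet label", call. = FALSE)
  structure(data.frame(face_index = face_index, facet_label = facet_label,
                       stringsAsFactors = FALSE),
            class = c("facet_annotation", "data.frame"))
}

#' @rdname facet_annotation
#' @param path CSV path with columns `face_index` (0-based), `facet_label`.
#' @export
read_facet_annotation <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("face_index", "facet_label") %in% names(d)))
    stop("annotation CSV needs columns face_index,facet_label", call. = FALSE)
  facet_annotation(d$face_index + 1L, d$facet_label)
}

#' @rdname facet_annotation
#' @param annotation a `facet_annotation`.
#' @export
write_facet_annotation <- function(annotation, path) {
  d <- data.frame(face_index = annotation$face_index - 1L,
                  facet_label = annotation$facet_label)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_annotation <- function(mesh, annotation, catalog) {
  if (any(annotation$face_index < 1L) ||
      any(annotation$face_index > nrow(mesh$faces)))
    stop("annotation references faces outside the mesh", call. = FALSE)
  missing <- setdiff(unique(annotation$facet_label), names(catalog))
  if (length(missing) > 0L)
    stop("facet label(s) missing from catalog: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Phase-classified wear-facet areas
#'
#' Measures the area of each annotated wear facet and totals them by power
#' stroke phase class. Tip-crush areas are measured but excluded from the
#' wear total used for the (BPI, LPI, PII) composition.
#'
#' @param mesh an aligned [triangle_mesh()].
#' @param annotation a [facet_annotation()].
#' @param catalog a [facet_catalog()].
#' @return list of class `facet_metrics`: `facets` (data.frame label, class,
#'   area_mm2), `class_totals` (named vector over BPI/LPI/PII/TIP_CRUSH),
#'   `wear_total` (BPI+LPI+PII area, mm^2).
#' @export
phase_areas <- function(mesh, annotation, catalog) {
  check_annotation(mesh, annotation, catalog)
  a <- triangle_areas(mesh$vertices, mesh$faces)
  labels <- unique(annotation$facet_label)
  facets <- data.frame(
    label = labels,
    class = as.character(catalog[labels]),
    area_mm2 = vapply(labels, function(lb)
      sum(a[annotation$face_index[annotation$facet_label == lb]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  cls <- c("BPI", "LPI", "PII", "TIP_CRUSH")
  totals <- vapply(cls, function(cc)
    sum(facets$area_mm2[facets$class == cc]), numeric(1))
  structure(list(facets = facets, class_totals = totals,
                 wear_total = sum(totals[c("BPI", "LPI", "PII")])),
            class = "facet_metrics")
}

#' Relative wear-facet area composition
#'
#' Expresses the (BPI, LPI, PII) phase areas as proportions of the total
#' wear-facet area (tip-crush excluded). A zero component is flagged as a
#' boundary composition (attribute `boundary`); the downstream log-ratio
#' transform applies the documented zero-replacement rule.
#'
#' @param areas a `facet_metrics` from [phase_areas()], or a numeric vector
#'   of three areas (BPI, LPI, PII).
#' @return named numeric vector (bpi, lpi, pii) summing to 1.
#' @export
wear_composition <- function(areas) {
  if (inherits(areas, "facet_metrics"))
    areas <- areas$class_totals[c("BPI", "LPI", "PII")]
  areas <- as.numeric(areas)
  stopifnot(length(areas) == 3L, all(areas >= 0))
  tot <- sum(areas)
  if (tot <= 0)
    stop("total wear-facet area is zero; composition undefined", call. = FALSE)
  p <- stats::setNames(areas / tot, c("bpi", "lpi", "pii"))
  attr(p, "boundary") <- any(p == 0)
  p
}

#' Dip angle of a wear facet
#'
#' Angle between the facet's total-least-squares plane and the cervical
#' reference plane, folded to [0, 90] degrees.
#'
#' @param mesh a [triangle_mesh()].
#' @param facet_faces integer vector of 1-based face indices of the facet.
#' @param cervical_plane a [plane3d()]; in the occlusal frame this is z = 0.
#' @return dip angle in degrees.
#' @export
dip_angle <- function(mesh, facet_faces, cervical_plane) {
  facet_faces <- as.integer(facet_faces)
  if (length(facet_faces) == 0L)
    stop("facet has no faces", call. = FALSE)
  vid <- unique(as.vector(mesh$faces[facet_faces, , drop = FALSE]))
  pts <- mesh$vertices[vid, , drop = FALSE]
  plane_angle(fit_plane(pts), cervical_plane)
}

#' Occlusal relief index
#'
#' Translates the cervical reference plane along its normal to the height of
#' the deepest point of the central fossa, cuts the crown there, and returns
#' the ratio of the 3D occlusal surface area above that plane to the 2D
#' crown cross-section area at it. 1.0 means a flat table; larger values mean
#' steeper occlusal relief.
#'
#' If `fossa_point` is omitted it is auto-detected as the lowest vertex
#' (along the cervical normal) among occlusally-facing faces, excluding
#' vertices within `outline_exclude` mm (in-plane) of the crown outline so
#' the cervical margin itself is never picked. An explicit `fossa_point`
#' always wins.
#'
#' @param mesh an aligned [triangle_mesh()].
#' @param cervical_plane a [plane3d()].
#' @param fossa_point optional 3-vector, the deepest point of the central
#'   fossa.
#' @param outline_exclude exclusion distance from the crown outline (mm).
#' @return list of class `ori_result`: `ori`, `area2d`, `area3d`,
#'   `fossa_point`.
#' @export
occlusal_relief_index <- function(mesh, cervical_plane, fossa_point = NULL,
                                  outline_exclude = 0.3) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(cervical_plane, "plane3d"))
  if (is.null(fossa_point)) {
    fossa_point <- detect_fossa(mesh, cervical_plane, outline_exclude)
  } else {
    fossa_point <- as.numeric(fossa_point)
  }
  cut_plane <- plane3d(cervical_plane$normal,
                       sum(cervical_plane$normal * fossa_point))
  cs <- cross_section_at_plane(mesh, cut_plane)
  if (cs$area2d <= 0)
    stop("crown cross-section at the fossa plane has zero area", call. = FALSE)
  ori <- cs$area3d_above / cs$area2d
  if (ori < 1) warning(sprintf("ORI %.4f < 1: unexpected for a crown mesh", ori))
  structure(list(ori = ori, area2d = cs$area2d, area3d = cs$area3d_above,
                 fossa_point = fossa_point),
            class = "ori_result")
}

# Lowest occlusally-facing vertex away from the crown outline. The outline is
# the set of mesh boundary vertices (edges with a single incident face).
detect_fossa <- function(mesh, cervical_plane, outline_exclude = 0.3) {
  up <- cervical_plane$normal
  nrm <- face_normals(mesh)
  occl_faces <- which(as.numeric(nrm %*% up) > 0)
  cand <- unique(as.vector(mesh$faces[occl_faces, , drop = FALSE]))
  bnd <- boundary_vertex_ids(mesh)
  if (length(bnd) > 0L && length(cand) > 0L) {
    # in-plane (xy in the occlusal frame) distance to the nearest outline vertex
    proj <- function(p) p - outer(plane_distance(cervical_plane, p), up)
    pc <- proj(mesh$vertices[cand, , drop = FALSE])
    pb <- proj(mesh$vertices[bnd, , drop = FALSE])
    d2 <- vapply(seq_len(nrow(pc)), function(i)
      min(colSums((t(pb) - pc[i, ])^2)), numeric(1))
    cand <- cand[sqrt(d2) >= outline_exclude]
  }
  if (length(cand) == 0L)
    stop("fossa auto-detection found no interior minimum; supply fossa_point",
         call. = FALSE)
  h <- plane_distance(cervical_plane, mesh$vertices[cand, , drop = FALSE])
  mesh$vertices[cand[which.min(h)], ]
}

boundary_vertex_ids <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  once <- names(which(table(key) == 1L))
  if (length(once) == 0L) return(integer(0))
  m <- do.call(rbind, strsplit(once, " "))
  unique(as.integer(m))
}

#' One specimen's wear-facet record
#'
#' @param specimen_id unique id.
#' @param group group label (e.g. `"pre-industrial"` / `"industrial"`).
#' @param sex one of `"F"`, `"M"`, `"indeterminate"`.
#' @param age_class one of `"younger"`, `"older"`, `"unknown"`.
#' @param composition (bpi, lpi, pii) proportions summing to 1.
#' @param dips named numeric (bpi, lpi, pii) mean dip angles in degrees.
#' @param ori occlusal relief index.
#' @return object of class `tooth_record`.
#' @export
tooth_record <- function(specimen_id, group, sex = "indeterminate",
                         age_class = "unknown", composition, dips, ori) {
  sex <- match.arg(sex, c("F", "M", "indeterminate"))
  age_class <- match.arg(age_class, c("younger", "older", "unknown"))
  composition <- as.numeric(composition)
  stopifnot(length(composition) == 3L,
            abs(sum(composition) - 1) < 1e-9,
            all(composition >= 0), all(composition <= 1))
  dips <- as.numeric(dips)
  stopifnot(length(dips) == 3L, all(dips >= 0 | is.na(dips)),
            all(dips <= 90 | is.na(dips)))
  structure(list(specimen_id = as.character(specimen_id),
                 group = as.character(group), sex = sex, age_class = age_class,
                 composition = composition, dips = dips, ori = as.numeric(ori)),
            class = "tooth_record")
}

#' Assemble per-specimen records into a metrics table
#'
#' One row per specimen with the composition on the percentage scale,
#' per-phase mean dip angles, ORI and covariates. The fixed CSV schema is
#' `specimen_id,group,sex,age_class,bpi_pct,lpi_pct,pii_pct,bpi_dip_deg,
#' lpi_dip_deg,pii_dip_deg,ori`.
#'
#' @param records list of [tooth_record()] objects.
#' @return data.frame of class `metrics_table`.
#' @export
build_metrics_table <- function(records) {
  stopifnot(length(records) >= 1L)
  ids <- vapply(records, function(r) r$specimen_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate specimen ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  d <- do.call(rbind, lapply(records, function(r)
    data.frame(specimen_id = r$specimen_id, group = r$group, sex = r$sex,
               age_class = r$age_class,
               bpi_pct = 100 * r$composition[1], lpi_pct = 100 * r$composition[2],
               pii_pct = 100 * r$composition[3],
               bpi_dip_deg = r$dips[1], lpi_dip_deg = r$dips[2],
               pii_dip_deg = r$dips[3], ori = r$ori,
               stringsAsFactors = FALSE)))
  rownames(d) <- NULL
  class(d) <- c("metrics_table", "data.frame")
  d
}

metrics_table_columns <- c("specimen_id", "group", "sex", "age_class",
                           "bpi_pct", "lpi_pct", "pii_pct", "bpi_dip_deg",
                           "lpi_dip_deg", "pii_dip_deg", "ori")

#' Read / write a metrics table CSV (6-decimal round-trip)
#' @param path CSV path.
#' @return a `metrics_table` data.frame.
#' @export
read_metrics_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(metrics_table_columns, names(d))
  if (length(missing) > 0L)
    stop("metrics CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  d <- d[, metrics_table_columns]
  class(d) <- c("metrics_table", "data.frame")
  d
}

#' @rdname read_metrics_table
#' @param table a `metrics_table`.
#' @export
write_metrics_table <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
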