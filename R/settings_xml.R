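#' Settings document
#'
#' Bundles everything the microscope needs to reproduce an experiment: the
#' scan program, the optional eye-exclusion ROI, the optional scan-axis
#' calibration, and a free-form map of device parameters (string keys to
#' scalar values). A timestamped copy is written beside every acquisition
#' run so sessions are reproducible.
#'
#' @param scan A [scan_config()].
#' @param eye_roi An [ellipse_roi()] or `NULL`.
#' @param calibration A [calibration_function()] or `NULL`.
#' @param device Named list of free-form device parameters (scalars).
#' @param timestamp Character timestamp; defaults to the current time.
#' @return An object of class `settings_document`.
#' @export
settings_document <- function(scan = scan_config(), eye_roi = NULL,
                              calibration = NULL, device = list(),
                              timestamp = format(Sys.time(),
                                                 "%Y-%m-%dT%H:%M:%S")) {
  validate_scan_config(scan)
  if (!is.null(eye_roi)) stopifnot(inherits(eye_roi, "ellipse_roi"))
  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "calibration_function"))
  }
  structure(list(scan = scan, eye_roi = eye_roi, calibration = calibration,
                 device = device, timestamp = timestamp),
            class = "settings_document")
}

# XML schema: flat key/value elements grouped under <scan>, <eye_roi>,
# <calibration>, <device> below a single <lsm_settings version="1"> root.
# Unknown top-level elements survive a load in the device map.
SETTINGS_SCHEMA_VERSION <- "1"

#' Save a settings document as XML
#'
#' Floats are serialized with round-trip precision, so save/load is the
#' identity on every numeric field.
#'
#' @param doc A [settings_document()].
#' @param path Output file path (UTF-8 XML).
#' @return `path`, invisibly.
#' @export
save_settings <- function(doc, path) {
  stopifnot(inherits(doc, "settings_document"))
  root <- xml2::xml_new_root("lsm_settings", version = SETTINGS_SCHEMA_VERSION,
                             timestamp = doc$timestamp)
  scan_node <- xml2::xml_add_child(root, "scan")
  for (f in names(doc$scan)) {
    val <- doc$scan[[f]]
    xml2::xml_add_child(scan_node, f,
                        if (is.numeric(val)) fmt_num(val) else as.character(val))
  }
  if (!is.null(doc$eye_roi)) {
    roi_node <- xml2::xml_add_child(root, "eye_roi")
    for (f in c("center_y", "center_z", "semi_y", "semi_z")) {
      xml2::xml_add_child(roi_node, f, fmt_num(doc$eye_roi[[f]]))
    }
  }
  if (!is.null(doc$calibration)) {
    cal_node <- xml2::xml_add_child(root, "calibration")
    for (i in seq_len(nrow(doc$calibration$knots))) {
      xml2::xml_add_child(cal_node, "knot",
                          do = fmt_num(doc$calibration$knots$do[i]),
                          volt = fmt_num(doc$calibration$knots$volt[i]))
    }
  }
  dev_node <- xml2::xml_add_child(root, "device")
  for (key in names(doc$device)) {
    val <- doc$device[[key]]
    xml2::xml_add_child(dev_node, key,
                        if (is.numeric(val)) fmt_num(val) else as.character(val))
  }
  ok <- tryCatch({
    xml2::write_xml(root, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write settings file '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Load a settings document from XML
#'
#' Mandatory scan fields are validated (missing ones are named in the
#' error); unknown top-level elements are preserved in the free-form
#' device map rather than dropped.
#'
#' @param path Path to a settings XML file.
#' @return A [settings_document()].
#' @export
load_settings <- function(path) {
  if (!file.exists(path)) stop("settings file does not exist: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed settings XML in '", path, "': ", conditionMessage(e))
  })
  if (xml2::xml_name(doc) != "lsm_settings") {
    stop("malformed settings XML: root element is <", xml2::xml_name(doc),
         ">, expected <lsm_settings>")
  }
  timestamp <- xml2::xml_attr(doc, "timestamp")

  scan_node <- xml2::xml_find_first(doc, "./scan")
  if (inherits(scan_node, "xml_missing")) {
    stop("settings XML missing mandatory <scan> element")
  }
  kids <- xml2::xml_children(scan_node)
  got <- stats::setNames(xml2::xml_text(kids), xml2::xml_name(kids))
  wanted <- scan_field_names()
  missing_fields <- setdiff(wanted, names(got))
  if (length(missing_fields) > 0) {
    stop("settings XML missing mandatory scan fields: ",
         paste(missing_fields, collapse = ", "))
  }
  scan_args <- lapply(wanted, function(f) {
    if (f == "mode") got[[f]] else as.numeric(got[[f]])
  })
  names(scan_args) <- wanted
  scan <- do.call(scan_config, scan_args)

  roi_node <- xml2::xml_find_first(doc, "./eye_roi")
  eye_roi <- NULL
  if (!inherits(roi_node, "xml_missing")) {
    g <- function(f) as.numeric(xml2::xml_text(
      xml2::xml_find_first(roi_node, paste0("./", f))))
    eye_roi <- ellipse_roi(g("center_y"), g("center_z"), g("semi_y"),
                           g("semi_z"))
  }

  cal_node <- xml2::xml_find_first(doc, "./calibration")
  calibration <- NULL
  if (!inherits(cal_node, "xml_missing")) {
    knots <- xml2::xml_find_all(cal_node, "./knot")
    calibration <- calibration_function(
      as.numeric(xml2::xml_attr(knots, "do")),
      as.numeric(xml2::xml_attr(knots, "volt")))
  }

  device <- list()
  dev_node <- xml2::xml_find_first(doc, "./device")
  if (!inherits(dev_node, "xml_missing")) {
    kids <- xml2::xml_children(dev_node)
    for (k in kids) device[[xml2::xml_name(k)]] <- parse_scalar(xml2::xml_text(k))
  }
  # unknown top-level elements are retained in the device map
  for (k in xml2::xml_children(doc)) {
    nm <- xml2::xml_name(k)
    if (!nm %in% c("scan", "eye_roi", "calibration", "device")) {
      device[[nm]] <- parse_scalar(xml2::xml_text(k))
    }
  }

  settings_document(scan = scan, eye_roi = eye_roi, calibration = calibration,
                    device = device, timestamp = timestamp)
}

parse_scalar <- function(s) {
  n <- suppressWarnings(as.numeric(s))
  if (!is.na(n) && fmt_num(n) == s) n else s
}

#' @export
print.settings_document <- function(x, ...) {
  cat(sprintf("<settings_document> saved %s\n", x$timestamp))
  print(x$scan)
  cat(sprintf("  eye ROI: %s; calibration: %s; %d device parameter(s)\n",
              if (is.null(x$eye_roi)) "absent" else "set",
              if (is.null(x$calibration)) "absent" else
                sprintf("%d knots", nrow(x$calibration$knots)),
              length(x$device)))
  invisible(x)
}
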