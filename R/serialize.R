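BUNDLE_SCHEMA_VERSION <- "1.0"

#' Write / read a case bundle
#'
#' A documented on-disk layout for one geometry and its solved records:
#' `manifest.json` (schema version, label, params, record table),
#' `centerline.csv` (x, y, z, s, region, area), `sections.json` (per-section
#' frame + boundary polygon) and `profiles.csv` (long table of per-point
#' pressure/WSS per record). Round-trips geometry and profiles to 1e-9;
#' metadata exactly.
#'
#' @param case a `case_geometry`.
#' @param records case-record tibble for this geometry (may be `NULL`).
#' @param path bundle directory (created if needed).
#' @return `path` invisibly (write); list with `case` and `records` (read).
#' @export
write_case_bundle <- function(case, records = NULL, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    schema_version = BUNDLE_SCHEMA_VERSION,
    label = case$label,
    spacing = case$spacing,
    params = as.list(case$params)
  )
  rec_tab <- NULL
  if (!is.null(records)) {
    rec_tab <- records[, setdiff(names(records), c("profile", "features", "targets"))]
    manifest$records <- rec_tab
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(format_full(case$centerline), file.path(path, "centerline.csv"),
            row.names = FALSE, quote = FALSE)
  sections <- lapply(case$sections, function(s) {
    list(index = s$index, region = s$region, area = s$area, origin = s$origin,
         normal = s$normal, e1 = s$e1, e2 = s$e2,
         boundary2d = unclass(s$boundary2d))
  })
  jsonlite::write_json(sections, file.path(path, "sections.json"), digits = NA,
                       auto_unbox = TRUE)
  if (!is.null(records)) {
    prof_long <- purrr::map2_dfr(seq_len(nrow(records)), records$profile,
                                 function(i, p) {
                                   tibble(record = i, index = p$index,
                                          s_mm = p$s_mm, region = p$region,
                                          pressure_mmHg = p$pressure_mmHg,
                                          wss_Pa = p$wss_Pa)
                                 })
    write.csv(format_full(prof_long), file.path(path, "profiles.csv"),
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

format_full <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) format(col, digits = 17, trim = TRUE, scientific = TRUE)
    else col
  }), stringsAsFactors = FALSE)
}

#' @rdname write_case_bundle
#' @export
read_case_bundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) abort(paste("no bundle manifest at", path))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$schema_version, BUNDLE_SCHEMA_VERSION)) {
    abort(sprintf("bundle schema mismatch: expected %s, found %s",
                  BUNDLE_SCHEMA_VERSION, manifest$schema_version %||% "<none>"))
  }
  cl <- read_checked_csv(file.path(path, "centerline.csv"),
                         c("x", "y", "z", "s", "region", "area"))
  cl <- as_tibble(cl)
  secs <- jsonlite::read_json(file.path(path, "sections.json"),
                              simplifyVector = FALSE)
  if (length(secs) != nrow(cl)) abort("bundle sections do not match centerline length")
  sections <- lapply(secs, function(s) {
    b2 <- do.call(rbind, lapply(s$boundary2d, function(row) as.numeric(unlist(row))))
    list(index = s$index, region = s$region, area = s$area,
         origin = as.numeric(unlist(s$origin)), normal = as.numeric(unlist(s$normal)),
         e1 = as.numeric(unlist(s$e1)), e2 = as.numeric(unlist(s$e2)),
         boundary2d = b2)
  })
  params <- as_tibble(manifest$params)
  case <- structure(list(label = manifest$label, params = params,
                         centerline = cl, sections = sections,
                         spacing = manifest$spacing),
                    class = "case_geometry")
  records <- NULL
  if (!is.null(manifest$records) && file.exists(file.path(path, "profiles.csv"))) {
    rec_tab <- as_tibble(manifest$records)
    prof <- read_checked_csv(file.path(path, "profiles.csv"),
                             c("record", "index", "s_mm", "region",
                               "pressure_mmHg", "wss_Pa"))
    profs <- lapply(seq_len(nrow(rec_tab)), function(i) {
      p <- as_tibble(prof[prof$record == i,
                          c("index", "s_mm", "region", "pressure_mmHg", "wss_Pa")])
      attr(p, "flow_rate") <- rec_tab$flow_rate[i]
      class(p) <- c("hemodynamic_profile", class(p))
      p
    })
    rec_tab$profile <- profs
    records <- rec_tab
  }
  list(case = case, records = records)
}

read_checked_csv <- function(path, expected_cols) {
  if (!file.exists(path)) abort(paste("missing bundle file:", path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort(paste0("parse error in ", path, ": ",
                                                  conditionMessage(e))))
  missing <- setdiff(expected_cols, names(df))
  if (length(missing)) {
    abort(paste0("malformed table ", path, ": missing columns ",
                 paste(missing, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(df[expected_cols]))
  if (length(bad)) {
    abort(sprintf("parse error in %s: incomplete row %d", path, bad[1]))
  }
  df
}

#' Save / load model checkpoints as JSON
#'
#' Weight arrays plus metadata, written as a single JSON document (text
#' only, full double precision). Works for both `shape_autoencoder` and
#' `aorta_surrogate` objects.
#'
#' @param model a trained model object.
#' @param path output file.
#' @return `path` invisibly (write); the model (read).
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "shape_autoencoder")) {
    payload <- list(type = "shape_autoencoder",
                    schema_version = BUNDLE_SCHEMA_VERSION,
                    m = model$m, grid_size = model$grid_size,
                    seed = model$seed, epochs = model$epochs,
                    loss_history = model$loss_history,
                    weights = list(W1 = model$W1, b1 = model$b1,
                                   W2 = model$W2, b2 = model$b2))
  } else if (inherits(model, "aorta_surrogate")) {
    payload <- list(type = "aorta_surrogate",
                    schema_version = BUNDLE_SCHEMA_VERSION,
                    config = unclass(model$config),
                    stats = model$stats,
                    loss_history = model$loss_history,
                    n_train = model$n_train,
                    weights = model$params)
  } else {
    abort("unsupported model type")
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) abort(paste("missing model checkpoint:", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema_version, BUNDLE_SCHEMA_VERSION)) {
    abort(sprintf("checkpoint schema mismatch: expected %s, found %s",
                  BUNDLE_SCHEMA_VERSION, payload$schema_version %||% "<none>"))
  }
  W <- lapply(payload$weights, as.matrix)
  if (identical(payload$type, "shape_autoencoder")) {
    return(structure(c(W, list(m = payload$m, grid_size = payload$grid_size,
                               loss_history = payload$loss_history,
                               seed = payload$seed, epochs = payload$epochs)),
                     class = "shape_autoencoder"))
  }
  if (identical(payload$type, "aorta_surrogate")) {
    cfg <- structure(payload$config, class = "surrogate_config")
    stats <- lapply(payload$stats, function(s) lapply(s, as.numeric))
    return(structure(list(params = W, config = cfg, stats = stats,
                          loss_history = payload$loss_history,
                          n_train = payload$n_train),
                     class = "aorta_surrogate"))
  }
  abort("unknown checkpoint type")
}
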