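# Feature schema for the longitudinal multiparametric MRI feature table.
#
# Every MRI follow-up session is summarised by 27 features: 3 region volumes,
# 6 perfusion ratios (normalised to contralateral normal-appearing white
# matter, so healthy tissue ~ 1), 6 diffusion-kurtosis parameters, 10
# metabolite ratios from chemical shift imaging over the contrast-enhancing
# region, a total-resection flag and a treatment-protocol group code.

.VOLUME_FEATURES   <- c("vol_CE", "vol_ED", "vol_N")
.PERFUSION_FEATURES <- c("rrCBV_CE", "rrCBV_ED", "rrCBF_CE", "rrCBF_ED",
                         "rDR_CE", "rDR_ED")
.DIFFUSION_FEATURES <- c("MK_CE", "MK_ED", "MD_CE", "MD_ED", "FA_CE", "FA_ED")
.SPECTRO_FEATURES  <- c("NAA_tCho", "NAA_sum", "tCho_sum", "NAA_Cre",
                        "Lips_tCho", "tCho_Cre", "Myo_sum", "Cre_sum",
                        "Lips_Cre", "Glx_sum")
.CLINICAL_FEATURES <- c("resection", "group")

#' Default 27-feature schema
#'
#' Builds the canonical feature schema used throughout the package: feature
#' names in fixed column order, the imaging modality of each feature, the set
#' of features guaranteed to be present at every session (the three region
#' volumes, the resection flag and the protocol-group code), and the tumour
#' region (`CE` contrast enhancement or `ED` perilesional oedema) each
#' modality feature is measured over. All ten spectroscopic ratios are
#' acquired over the contrast-enhancing region, so their region is `CE`.
#'
#' @return An object of class `gbm_schema`: a list with elements
#'   `names` (character, length 27, fixed order), `modality` (named character,
#'   one of `"volume"`, `"perfusion"`, `"diffusion"`, `"spectroscopy"`,
#'   `"clinical"`), `always_present` (character, length 5), and `region`
#'   (named character, `"CE"`, `"ED"` or `NA` for features not tied to a
#'   tumour region).
#' @export
#' @examples
#' s <- gbm_schema()
#' length(s$names)                # 27
#' s$always_present               # volumes + resection + group
gbm_schema <- function() {
  names <- c(.VOLUME_FEATURES, .PERFUSION_FEATURES, .DIFFUSION_FEATURES,
             .SPECTRO_FEATURES, .CLINICAL_FEATURES)
  modality <- c(
    stats::setNames(rep("volume", 3L), .VOLUME_FEATURES),
    stats::setNames(rep("perfusion", 6L), .PERFUSION_FEATURES),
    stats::setNames(rep("diffusion", 6L), .DIFFUSION_FEATURES),
    stats::setNames(rep("spectroscopy", 10L), .SPECTRO_FEATURES),
    stats::setNames(rep("clinical", 2L), .CLINICAL_FEATURES)
  )
  region <- stats::setNames(rep(NA_character_, length(names)), names)
  region[grepl("_CE$", names)] <- "CE"
  region[grepl("_ED$", names)] <- "ED"
  # spectroscopic ratios are measured over the contrast-enhancing region
  region[.SPECTRO_FEATURES] <- "CE"
  region[.VOLUME_FEATURES] <- NA_character_
  structure(
    list(
      names = names,
      modality = modality,
      always_present = c(.VOLUME_FEATURES, .CLINICAL_FEATURES),
      region = region
    ),
    class = "gbm_schema"
  )
}

#' @export
print.gbm_schema <- function(x, ...) {
  cat("<gbm_schema> ", length(x$names), " features\n", sep = "")
  for (m in unique(x$modality)) {
    cat(sprintf("  %-12s %s\n", m,
                paste(x$names[x$modality == m], collapse = ", ")))
  }
  invisible(x)
}

# Volume column associated with a tumour region code.
region_volume_feature <- function(region) {
  switch(region, CE = "vol_CE", ED = "vol_ED",
         stop("no volume feature for region '", region, "'", call. = FALSE))
}

#' Feature names of a modality subset
#'
#' @param schema a [gbm_schema()].
#' @param modality one of `"all"`, `"perfusion"`, `"diffusion"`,
#'   `"spectroscopy"`.
#' @param keep_clinical retain the two always-present clinical features
#'   (resection flag, group code) alongside the modality block. Default `TRUE`.
#' @return Character vector of feature names in schema order.
#' @export
modality_features <- function(schema, modality, keep_clinical = TRUE) {
  stopifnot(inherits(schema, "gbm_schema"))
  modality <- match.arg(modality,
                        c("all", "perfusion", "diffusion", "spectroscopy"))
  if (modality == "all") return(schema$names)
  keep <- schema$modality == modality
  if (keep_clinical) keep <- keep | schema$modality == "clinical"
  schema$names[keep]
}

#' Write / read a schema description file
#'
#' Serialises the schema (feature name, modality, always-present flag, region)
#' as YAML for audit and interchange.
#'
#' @param schema a [gbm_schema()].
#' @param path file path.
#' @return `write_schema` returns `path` invisibly; `read_schema` returns a
#'   `gbm_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "gbm_schema"))
  yaml::write_yaml(list(
    features = lapply(seq_along(schema$names), function(i) {
      f <- schema$names[i]
      list(name = f,
           modality = unname(schema$modality[f]),
           always_present = f %in% schema$always_present,
           region = if (is.na(schema$region[f])) NULL else unname(schema$region[f]))
    })
  ), path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  spec <- yaml::read_yaml(path)$features
  names <- vapply(spec, `[[`, "", "name")
  modality <- stats::setNames(vapply(spec, `[[`, "", "modality"), names)
  region <- stats::setNames(vapply(spec, function(s) {
    if (is.null(s$region)) NA_character_ else s$region
  }, ""), names)
  always <- names[vapply(spec, `[[`, NA, "always_present")]
  out <- structure(list(names = names, modality = modality,
                        always_present = always, region = region),
                   class = "gbm_schema")
  validate_schema(out)
  out
}

validate_schema <- function(schema) {
  ref <- gbm_schema()
  if (!identical(schema$names, ref$names))
    gbm_abort("schema must list the 27 canonical features in order",
              "gbm_schema_error")
  if (!setequal(schema$always_present, ref$always_present))
    gbm_abort("schema always-present set must be the 3 volumes, resection and group",
              "gbm_schema_error")
  invisible(schema)
}

# Classed condition helper: all package validation errors carry a condition
# class so callers can test for the failure mode, not the message.
gbm_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gbm_error")))
}
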