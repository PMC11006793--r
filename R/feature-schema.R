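#' @title Feature vector schemas
#' @description
#' A schema is an ordered list of named components defining the layout of an
#' encoded feature vector. Three schemas ship with the package:
#'
#' * `"complete"` (1169-dim): orf_length (1), 1-mer (4), 2-mer (16),
#'   nucleotide_bias (6), hexamer_score (1), codon_bias (1), fickett (4),
#'   3-mer (64), 4-mer (256), 1-gap (16), 2-gap (16), 3-gap (16),
#'   1-bigap (256), 2-bigap (256), 3-bigap (256);
#' * `"reduced33"` (33-dim): the first seven components — the k-mer/g-gap
#'   blocks, which feature ablation shows to be dispensable, are dropped;
#' * `"final32"` (32-dim): the reduced33 features reordered by their shipped
#'   mRMR ranking with the lowest-ranked feature (2-mer TT) removed, the
#'   default for trained models.
#' @name feature_schema
NULL

COMPONENT_DIMS <- c(
  orf_length = 1L, mer1 = 4L, mer2 = 16L, nucleotide_bias = 6L,
  hexamer_score = 1L, codon_bias = 1L, fickett = 4L,
  mer3 = 64L, mer4 = 256L, gap1 = 16L, gap2 = 16L, gap3 = 16L,
  bigap1 = 256L, bigap2 = 256L, bigap3 = 256L
)

# shipped mRMR ranking of the 33 reduced-schema features (rank 1 first);
# final32 drops the last entry
RANKED33_FEATURES <- c(
  "orf_length", "nb_-3", "fickett_T", "fickett_A", "fickett_C", "fickett_G",
  "mer2_CG", "mer2_GA", "mer2_CC", "mer2_TA", "mer2_CT", "mer2_AT",
  "mer2_GC", "mer2_GG", "mer2_GT", "mer2_TC", "mer2_TG", "mer2_CA",
  "mer1_T", "mer2_AG", "nb_4", "nb_5", "hexamer_score", "codon_bias",
  "nb_-2", "nb_-1", "mer2_AC", "mer2_AA", "nb_6", "mer1_A", "mer1_C",
  "mer1_G", "mer2_TT"
)

component_feature_names <- function(component) {
  switch(component,
    orf_length = "orf_length",
    mer1 = paste0("mer1_", all_kmers(1L)),
    mer2 = paste0("mer2_", all_kmers(2L)),
    mer3 = paste0("mer3_", all_kmers(3L)),
    mer4 = paste0("mer4_", all_kmers(4L)),
    nucleotide_bias = paste0("nb_", TIS_SITES),
    hexamer_score = "hexamer_score",
    codon_bias = "codon_bias",
    fickett = paste0("fickett_", c("T", "A", "C", "G")),
    gap1 = gap_pattern_names(1L, "gap"),
    gap2 = gap_pattern_names(2L, "gap"),
    gap3 = gap_pattern_names(3L, "gap"),
    bigap1 = gap_pattern_names(1L, "bigap"),
    bigap2 = gap_pattern_names(2L, "bigap"),
    bigap3 = gap_pattern_names(3L, "bigap"),
    stop("unknown feature component: ", component)
  )
}

gap_pattern_names <- function(g, mode) {
  k <- if (mode == "gap") 1L else 2L
  units <- all_kmers(k)
  prefix <- if (mode == "gap") paste0("gap", g) else paste0("bigap", g)
  as.vector(t(outer(units, units, function(x, y) {
    paste0(prefix, "_", x, ".", y)
  })))
}

#' Retrieve or build a feature schema
#'
#' @param name `"complete"`, `"reduced33"` or `"final32"`.
#' @return a `feature_schema` list with `name`, `components` (data.frame of
#'   `component`, `dim`) and `feature_names` (full ordered vector layout).
#' @export
feature_schema <- function(name = c("final32", "reduced33", "complete")) {
  name <- match.arg(name)
  comps <- switch(name,
    complete = names(COMPONENT_DIMS),
    reduced33 = names(COMPONENT_DIMS)[1:7],
    final32 = head(RANKED33_FEATURES, -1L)
  )
  if (name == "final32") {
    return(feature_schema_from_features(comps, name = name))
  }
  structure(list(
    name = name,
    components = data.frame(component = comps,
                            dim = unname(COMPONENT_DIMS[comps]),
                            stringsAsFactors = FALSE),
    feature_names = unlist(lapply(comps, component_feature_names),
                           use.names = FALSE)
  ), class = "feature_schema")
}

#' Build a schema from individual reduced-schema feature names
#'
#' Each named feature becomes a 1-dim component; used for mRMR-IFS subsets
#' and the shipped `"final32"` schema.
#'
#' @param features character vector of feature names drawn from the
#'   `"reduced33"` layout (e.g. `"orf_length"`, `"nb_-3"`, `"mer2_CG"`).
#' @param name schema name.
#' @return a `feature_schema`.
#' @export
feature_schema_from_features <- function(features, name = "custom") {
  reduced <- unlist(lapply(names(COMPONENT_DIMS)[1:7],
                           component_feature_names), use.names = FALSE)
  bad <- setdiff(features, reduced)
  if (length(bad) > 0L) {
    stop("unknown feature name(s): ", paste(bad, collapse = ", "))
  }
  structure(list(
    name = name,
    components = data.frame(component = features,
                            dim = rep.int(1L, length(features)),
                            stringsAsFactors = FALSE),
    feature_names = features
  ), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", x$name, ": ",
      length(x$feature_names), " features, ",
      nrow(x$components), " components\n", sep = "")
  invisible(x)
}

#' Schema dimension
#' @param schema a `feature_schema`.
#' @return total number of features.
#' @export
schema_dim <- function(schema) length(schema$feature_names)

#' Serialize a schema to JSON
#' @param schema a `feature_schema`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_schema <- function(schema, path) {
  jsonlite::write_json(list(format = "smorfcp_feature_schema", version = 1L,
                            name = schema$name,
                            components = schema$components),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a schema from JSON
#' @param path a file written by [write_feature_schema()].
#' @return a `feature_schema`.
#' @export
read_feature_schema <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "smorfcp_feature_schema")) {
    stop("not a smorfcp feature-schema document: ", path)
  }
  comps <- doc$components$component
  if (all(comps %in% names(COMPONENT_DIMS))) {
    structure(list(name = doc$name,
                   components = doc$components,
                   feature_names = unlist(lapply(comps,
                                                 component_feature_names),
                                          use.names = FALSE)),
              class = "feature_schema")
  } else {
    feature_schema_from_features(comps, name = doc$name)
  }
}
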