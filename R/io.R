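#' @title File formats
#' @description
#' All tabular artifacts are tab-separated, header row, UTF-8, '.' decimal,
#' no index column. The model store is a single JSON file with a `weights`
#' table, an `extra` table and a `build_id`, mirroring the relational
#' layout of public TWAS prediction-model databases. Writers are
#' deterministic given identical inputs and embed provenance metadata in
#' `#`-prefixed header lines where the format allows it.
#' @name twasvc-io
NULL

meta_header <- function(meta) {
  paste0("#twasvc ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
}

read_meta_header <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#twasvc ")) {
    jsonlite::fromJSON(sub("^#twasvc ", "", first))
  } else NULL
}

write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(meta_header(meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, na.strings = c("NA", ""), ...)
}

#' Write / read a dosage matrix as TSV
#'
#' Plain tab-delimited matrix with a one-line header of variant ids and a
#' `#`-prefixed provenance line (standardized flag, allele frequencies).
#'
#' @param G A `genotype_matrix`.
#' @param path Output path.
#' @return `write_genotypes` returns `path` invisibly; `read_genotypes`
#'   returns a `genotype_matrix`.
#' @export
write_genotypes <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  meta <- list(format = "dosage_matrix", standardized = G$standardized,
               allele_freqs = G$allele_freqs)
  df <- as.data.frame(G$dosages)
  names(df) <- G$variant_ids
  write_tsv(df, path, meta = meta)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  meta <- read_meta_header(path)
  df <- read_tsv(path, check.names = FALSE)
  genotype_matrix(as.matrix(df), variant_ids = names(df),
                  allele_freqs = meta$allele_freqs,
                  standardized = isTRUE(meta$standardized))
}

#' Read a VCF as a dosage matrix (optional)
#'
#' Maps VCF genotypes to dosages: the `DS` FORMAT field is preferred;
#' otherwise `GT` alleles are summed. Requires the `vcfR` package.
#'
#' @param path Path to a (possibly compressed) VCF.
#' @return A `genotype_matrix` (individuals x variants, raw dosages).
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF dosages requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- v@fix[, "ID"]
  anon <- is.na(ids) | ids == "."
  ids[anon] <- paste0(v@fix[, "CHROM"], ":", v@fix[, "POS"])[anon]
  has_ds <- any(grepl("DS", v@gt[, 1]))
  if (has_ds) {
    d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    d <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  genotype_matrix(t(d), variant_ids = ids, standardized = FALSE)
}

#' Write / read mediator prediction weights
#'
#' TSV dialect: columns `mediator_id`, `variant_id`, `ref_allele`,
#' `alt_allele`, `weight`. Zero-weight rows are dropped on read with a
#' logged count; duplicate (mediator, variant) rows are an error.
#'
#' @param weights A list of `weight_set` objects (or one).
#' @param path File path.
#' @param format `"tsv"` or `"store"` (single-file JSON model store, see
#'   [read_model_store()]).
#' @return `read_weights` returns a list of `weight_set`s; the model-store
#'   metadata, when present, is attached as attribute `"model_store"`.
#' @export
write_weights <- function(weights, path, format = c("tsv", "store")) {
  format <- match.arg(format)
  if (inherits(weights, "weight_set")) weights <- list(weights)
  df <- weights_to_table(weights)
  if (format == "tsv") {
    write_tsv(df, path)
  } else {
    store <- model_store(
      build_id = weights[[1]]$build_id %||% "unversioned",
      weights_table = df,
      extra_table = data.frame(
        mediator_id = vapply(weights, `[[`, character(1), "mediator_id"),
        n_model_variants = vapply(weights, `[[`, numeric(1),
                                  "n_model_variants"),
        phi = NA_real_, phi_se = NA_real_,
        stringsAsFactors = FALSE
      )
    )
    write_model_store(store, path)
  }
  invisible(path)
}

weights_to_table <- function(weights) {
  do.call(rbind, lapply(weights, function(w) {
    keep <- w$weights != 0
    data.frame(
      mediator_id = w$mediator_id,
      variant_id = w$variant_ids[keep],
      ref_allele = (w$ref_allele %||% rep(NA_character_,
                                          length(w$weights)))[keep],
      alt_allele = (w$alt_allele %||% rep(NA_character_,
                                          length(w$weights)))[keep],
      weight = w$weights[keep],
      stringsAsFactors = FALSE
    )
  }))
}

table_to_weights <- function(df, build_id = NULL) {
  if (anyDuplicated(df[, c("mediator_id", "variant_id")])) {
    stop("duplicate (mediator_id, variant_id) rows in weight table")
  }
  n_zero <- sum(df$weight == 0)
  if (n_zero > 0) {
    message("dropping ", n_zero, " zero-weight row(s)")
    df <- df[df$weight != 0, , drop = FALSE]
  }
  lapply(split(df, df$mediator_id), function(d) {
    weight_set(d$mediator_id[1], d$variant_id, d$weight,
               ref_allele = d$ref_allele, alt_allele = d$alt_allele,
               build_id = build_id)
  })
}

#' @rdname write_weights
#' @export
read_weights <- function(path, format = c("tsv", "store")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv(path)
    need <- c("mediator_id", "variant_id", "weight")
    if (!all(need %in% names(df))) {
      stop("weight TSV must have columns: ", paste(need, collapse = ", "))
    }
    if (!"ref_allele" %in% names(df)) df$ref_allele <- NA_character_
    if (!"alt_allele" %in% names(df)) df$alt_allele <- NA_character_
    table_to_weights(df)
  } else {
    store <- read_model_store(path)
    out <- table_to_weights(store$weights_table, build_id = store$build_id)
    attr(out, "model_store") <- store[c("build_id", "extra_table")]
    out
  }
}

#' PredictDB-style single-file model store
#'
#' A relational bundle of per-mediator prediction weights (`weights_table`:
#' `mediator_id`, `variant_id`, `ref_allele`, `alt_allele`, `weight`) and
#' per-mediator metadata (`extra_table`: `mediator_id`,
#' `n_model_variants`, optional `phi`, `phi_se`), tagged with a `build_id`
#' so that weights and inflation slopes from different model builds are
#' never silently mixed. Serialized as a single JSON text file.
#'
#' @param build_id Character build identifier.
#' @param weights_table,extra_table Data frames as described above; every
#'   mediator must appear in both.
#' @return A `model_store`.
#' @export
model_store <- function(build_id, weights_table, extra_table) {
  stopifnot(is.character(build_id), length(build_id) == 1L)
  wm <- unique(weights_table$mediator_id)
  em <- unique(extra_table$mediator_id)
  if (anyDuplicated(em)) stop("duplicate mediator_id in extra_table")
  if (!setequal(wm, em)) {
    stop("model store tables disagree: mediators ",
         paste(utils::head(c(setdiff(wm, em), setdiff(em, wm)), 3),
               collapse = ", "),
         " are not present in both weights_table and extra_table")
  }
  if ("phi" %in% names(extra_table) &&
      any(extra_table$phi < 0, na.rm = TRUE)) {
    stop("extra_table phi values must be >= 0")
  }
  structure(list(build_id = build_id, weights_table = weights_table,
                 extra_table = extra_table),
            class = "model_store")
}

#' @rdname model_store
#' @param store A `model_store`.
#' @param path File path.
#' @export
write_model_store <- function(store, path) {
  stopifnot(inherits(store, "model_store"))
  jsonlite::write_json(
    list(format = "twasvc_model_store", build_id = store$build_id,
         weights = store$weights_table, extra = store$extra_table),
    path, dataframe = "columns", auto_unbox = TRUE, digits = NA, na = "null",
    pretty = TRUE
  )
  invisible(path)
}

#' @rdname model_store
#' @export
read_model_store <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (is.null(x$format) || x$format != "twasvc_model_store") {
    stop("not a twasvc model store: ", path)
  }
  model_store(x$build_id, as.data.frame(x$weights), as.data.frame(x$extra))
}

#' @export
print.model_store <- function(x, ...) {
  cat("model_store (build ", x$build_id, "): ",
      length(unique(x$extra_table$mediator_id)), " mediators, ",
      nrow(x$weights_table), " weight rows",
      if ("phi" %in% names(x$extra_table) &&
          any(!is.na(x$extra_table$phi))) ", phi attached" else "",
      "\n", sep = "")
  invisible(x)
}

#' Write inflation-slope estimates
#'
#' Always writes a TSV (`mediator_id`, `phi`, `phi_raw`, `se`, `intercept`,
#' `clamped`, `n_cells`, `reps`). When a model store is supplied, the
#' `phi`/`phi_se` columns of its `extra` table are upserted by
#' `mediator_id`; a `build_id` mismatch between the estimates and the store
#' is an error (no silent cross-build mixing).
#'
#' @param estimates A `phi_estimate`, a list of them, or a data.frame with
#'   the columns above.
#' @param path Output TSV path.
#' @param store Optional [model_store()] to update.
#' @param store_path Optional path to write the updated store to.
#' @return Invisibly, the (possibly updated) store, or `NULL`.
#' @export
write_phi <- function(estimates, path, store = NULL, store_path = NULL) {
  df <- phi_to_table(estimates)
  if (nrow(df) == 0L) stop("no inflation-slope estimates to write")
  write_tsv(df, path)
  if (is.null(store)) return(invisible(NULL))
  stopifnot(inherits(store, "model_store"))
  builds <- attr(df, "build_ids")
  known <- builds[!is.na(builds)]
  if (length(known) > 0 && any(known != store$build_id)) {
    stop("build_id mismatch: estimates come from build ",
         unique(known)[1], " but the store is build ", store$build_id)
  }
  missing <- setdiff(df$mediator_id, store$extra_table$mediator_id)
  if (length(missing) > 0) {
    stop("mediator(s) not in the model store: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  idx <- match(df$mediator_id, store$extra_table$mediator_id)
  store$extra_table$phi[idx] <- df$phi
  store$extra_table$phi_se[idx] <- df$se
  if (!is.null(store_path)) write_model_store(store, store_path)
  invisible(store)
}

phi_to_table <- function(estimates) {
  if (inherits(estimates, "phi_estimate")) estimates <- list(estimates)
  if (is.data.frame(estimates)) {
    builds <- rep(NA_character_, nrow(estimates))
    attr(estimates, "build_ids") <- builds
    return(estimates)
  }
  stopifnot(all(vapply(estimates, inherits, logical(1), "phi_estimate")))
  df <- data.frame(
    mediator_id = vapply(estimates, `[[`, character(1), "mediator_id"),
    phi = vapply(estimates, `[[`, numeric(1), "phi"),
    phi_raw = vapply(estimates, `[[`, numeric(1), "phi_raw"),
    se = vapply(estimates, `[[`, numeric(1), "se"),
    intercept = vapply(estimates, `[[`, numeric(1), "intercept"),
    clamped = vapply(estimates, `[[`, logical(1), "clamped"),
    n_cells = vapply(estimates, function(e) nrow(e$cells), numeric(1)),
    reps = vapply(estimates, `[[`, numeric(1), "n_reps_per_cell"),
    stringsAsFactors = FALSE
  )
  attr(df, "build_ids") <- vapply(estimates, function(e)
    e$build_id %||% NA_character_, character(1))
  df
}

#' Read an inflation-slope TSV
#'
#' @param path Path written by [write_phi()] (columns `mediator_id`,
#'   `phi`, ...).
#' @return A data.frame.
#' @export
read_phi <- function(path) {
  df <- read_tsv(path)
  if (!all(c("mediator_id", "phi") %in% names(df))) {
    stop("phi table must have columns mediator_id and phi")
  }
  df
}

#' Write / read a TWAS result table
#'
#' Tab-delimited with columns `mediator_id`, `n`, `beta_hat`, `se`, `z`,
#' `p`, `phi`, `correction_factor`, `z_corrected`, `p_corrected`; missing
#' corrections are written as empty fields, never 0.
#'
#' @param results A TWAS result data.frame.
#' @param path File path.
#' @return `read_results` returns the data.frame.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  write_tsv(results, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- read_tsv(path)
  if (!all(c("mediator_id", "z", "p") %in% names(df))) {
    stop("result table must have at least mediator_id, z, p")
  }
  df
}

#' Read a JSON or YAML configuration file
#'
#' Key-value configuration for the simulators and the command-line
#' interface; the parsed config is echoed into output metadata by the
#' writers for provenance.
#'
#' @param path Path ending in `.json`, `.yaml` or `.yml`.
#' @return A named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::fromJSON(path)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs require the yaml package; use JSON otherwise")
    }
    yaml::read_yaml(path)
  } else {
    stop("unknown config format: .", ext, " (use .json or .yaml)")
  }
}
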