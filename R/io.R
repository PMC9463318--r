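#' Read a patient-record CSV for a given network
#'
#' The CSV contract mirrors clinical extraction practice: a mandatory header
#' whose column names match node names, and cell values matching state labels,
#' both case-sensitively; no missing cells; comma separator, UTF-8, no quoting
#' of state labels (labels may not contain commas).
#'
#' @param path CSV file path.
#' @param net A `bn` object the dataset must match.
#' @return Validated data.frame (provenance `"file"`).
#' @export
read_dataset_csv <- function(path, net) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  data <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  validate_dataset(net, data, require_all = FALSE)
  message(sprintf("read %d records x %d columns from %s", nrow(data), ncol(data), path))
  attr(data, "provenance") <- "file"
  data
}

#' Write a patient-record CSV
#'
#' @param data Data.frame of state labels.
#' @param path Output path.
#' @export
write_dataset_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

MODEL_SCHEMA <- "opsccbn-model/1"

#' Serialize a network to JSON
#'
#' Lossless round trip: variables (with state order and role), edges, CPT rows
#' at full precision in declared state order, `fixed` flags and metadata.
#'
#' @param net A `bn` object.
#' @param path Output path.
#' @param metadata Optional named list (title, provenance notes, abstraction
#'   history).
#' @export
write_model_json <- function(net, path, metadata = list()) {
  doc <- list(
    schema = MODEL_SCHEMA,
    metadata = metadata,
    variables = lapply(unname(net$variables), function(v)
      list(name = v$name, states = as.list(v$states), role = v$role)),
    edges = apply(bn_edges(net), 1L, function(e) as.list(unname(e)), simplify = FALSE),
    cpts = lapply(bn_names(net), function(v) {
      cpt <- net$cpts[[v]]
      list(child = v, parents = as.list(cpt$parents),
           fixed = isTRUE(cpt$fixed),
           rows = lapply(seq_len(nrow(cpt$prob)), function(i) as.list(unname(cpt$prob[i, ]))))
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Load a network from JSON
#'
#' Validates the document schema and every CPT. Rows whose sum deviates from
#' 1 by at most `1e-6` are renormalized (tolerated serialization noise);
#' larger deviations are an error.
#'
#' @param path JSON file path.
#' @return A `bn` object.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema, MODEL_SCHEMA)) {
    stop(sprintf("unsupported or missing schema field (expected '%s')", MODEL_SCHEMA),
         call. = FALSE)
  }
  for (field in c("variables", "edges", "cpts")) {
    if (is.null(doc[[field]])) stop(sprintf("model document lacks field '%s'", field),
                                    call. = FALSE)
  }
  vars <- lapply(doc$variables, function(v) {
    if (is.null(v$name) || is.null(v$states)) {
      stop("variable entry lacks field 'name' or 'states'", call. = FALSE)
    }
    bn_variable(v$name, unlist(v$states), if (is.null(v$role)) "diagnostic" else v$role)
  })
  edges <- if (length(doc$edges)) {
    do.call(rbind, lapply(doc$edges, function(e) c(e[[1L]], e[[2L]])))
  } else NULL
  net <- bn_network(vars, edges)
  for (entry in doc$cpts) {
    child <- entry$child
    if (is.null(child) || !child %in% bn_names(net)) {
      stop(sprintf("CPT entry names unknown variable '%s'", child), call. = FALSE)
    }
    parents <- as.character(unlist(entry$parents))
    if (!identical(sort(parents), sort(net$parents[[child]]))) {
      stop(sprintf("CPT parents for '%s' do not match the edge set", child), call. = FALSE)
    }
    prob <- do.call(rbind, lapply(entry$rows, function(r) as.numeric(unlist(r))))
    sums <- rowSums(prob)
    off <- abs(sums - 1)
    if (any(off > 1e-6)) {
      stop(sprintf("CPT for '%s': row %d sums to %.8f (beyond the 1e-6 load tolerance)",
                   child, which.max(off), sums[which.max(off)]), call. = FALSE)
    }
    renorm <- off > 1e-9  # leave clean rows bit-identical for round-trip stability
    prob[renorm, ] <- prob[renorm, , drop = FALSE] / sums[renorm]
    dimnames(prob) <- list(NULL, net$variables[[child]]$states)
    # reorder parent dimension if serialized parent order differs
    if (!identical(parents, net$parents[[child]])) {
      net$parents[[child]] <- parents
    }
    net$cpts[[child]] <- new_cpt(child, parents, prob, fixed = isTRUE(entry$fixed))
  }
  validate_network(net)
  net
}

xdsl_id <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[0-9]", x), paste0("s", x), x)
}

#' Export a network to GeNIe-compatible XDSL
#'
#' Minimal XDSL dialect: one `cpt` element per node carrying `state` elements
#' in declared order, a `parents` element, and the probability list in
#' row-major parent order (first parent varying slowest, child states varying
#' fastest). Export-only; ids are sanitized to XDSL identifier rules (state
#' labels starting with a digit get an `s` prefix).
#'
#' @param net A `bn` object.
#' @param path Output path.
#' @export
export_xdsl <- function(net, path) {
  doc <- xml2::xml_new_root("smile", version = "1.0", id = "opsccbn_export",
                            numsamples = "10000")
  nodes <- xml2::xml_add_child(doc, "nodes")
  for (v in topo_order(net)) {
    cpt <- net$cpts[[v]]
    el <- xml2::xml_add_child(nodes, "cpt", id = xdsl_id(v))
    for (s in net$variables[[v]]$states) {
      xml2::xml_add_child(el, "state", id = xdsl_id(s))
    }
    if (length(cpt$parents)) {
      xml2::xml_add_child(el, "parents", paste(xdsl_id(cpt$parents), collapse = " "))
    }
    grid <- parent_config_grid(bn_card(net, cpt$parents))
    perm <- if (ncol(grid)) do.call(order, as.data.frame(grid)) else 1L
    flat <- as.vector(t(cpt$prob[perm, , drop = FALSE]))
    xml2::xml_add_child(el, "probabilities",
                        paste(format(flat, digits = 17, scientific = FALSE, trim = TRUE),
                              collapse = " "))
  }
  xml2::xml_add_child(doc, "extensions")
  xml2::write_xml(doc, path)
  invisible(path)
}

## YAML parses bare true/false/yes/no as logicals; state labels live as
## strings, so coerce scalars back.
yaml_chr <- function(x) {
  if (is.list(x)) lapply(x, yaml_chr)
  else if (is.logical(x)) ifelse(x, "true", "false")
  else x
}

#' Read an abstraction recipe from YAML
#'
#' @param path YAML file with a top-level `steps` list; each step carries an
#'   `op` field (`merge`, `condense`, `add_edge`, `resolve_transitivity`,
#'   `binarize`, `noisy_or`) and its parameters, see [replay_recipe()].
#' @return List of step specifications.
#' @export
read_recipe_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  steps <- if (!is.null(doc$steps)) doc$steps else doc
  lapply(steps, function(st) {
    st[setdiff(names(st), c("links", "leak"))] <-
      yaml_chr(st[setdiff(names(st), c("links", "leak"))])
    st
  })
}

#' Write an abstraction recipe to YAML
#'
#' @param recipe List of step specifications.
#' @param path Output path.
#' @export
write_recipe_yaml <- function(recipe, path) {
  yaml::write_yaml(list(steps = recipe), path)
  invisible(path)
}

#' Export a cross-validation report as JSON
#'
#' @param cv A `bn_cv` object.
#' @param path Output path.
#' @export
write_report_json <- function(cv, path) {
  doc <- list(
    k = cv$k, seed = cv$seed, alpha = cv$alpha,
    n_records = cv$n_records, targets = cv$targets,
    overall = list(correct = cv$overall_correct, total = cv$overall_total,
                   accuracy = cv$accuracy),
    per_target = cv$per_target,
    per_fold = stats::aggregate(correct ~ fold, data = cv$scores, FUN = sum) |>
      merge(stats::aggregate(correct ~ fold, data = cv$scores, FUN = length),
            by = "fold", suffixes = c("", "_total"))
  )
  names(doc$per_fold) <- c("fold", "correct", "total")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path, useBytes = TRUE)
  invisible(path)
}

#' Export ROC points as CSV
#'
#' Columns `target`, `threshold`, `fpr`, `tpr` for every evaluated target.
#'
#' @param cv A `bn_cv` object.
#' @param path Output path.
#' @export
write_roc_csv <- function(cv, path) {
  rows <- do.call(rbind, lapply(names(cv$roc), function(t) {
    cbind(target = t, cv$roc[[t]])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plain-text cross-validation report table
#'
#' @param cv A `bn_cv` object.
#' @return Character vector of report lines (also usable via `writeLines`).
#' @export
format_report <- function(cv) {
  c(sprintf("%d-fold cross-validation | %d records x %d targets | alpha = %g | seed = %d",
            cv$k, cv$n_records, length(cv$targets), cv$alpha, cv$seed),
    sprintf("overall accuracy %.3f (%d/%d)", cv$accuracy, cv$overall_correct,
            cv$overall_total),
    "",
    sprintf("%-32s %8s %8s %9s %6s", "target", "correct", "total", "accuracy", "auc"),
    vapply(seq_len(nrow(cv$per_target)), function(i) {
      r <- cv$per_target[i, ]
      sprintf("%-32s %8d %8d %9.3f %6s", r$target, r$correct, r$total, r$accuracy,
              if (r$degenerate || is.na(r$auc)) "undef" else sprintf("%.3f", r$auc))
    }, ""))
}
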