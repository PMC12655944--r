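#' Define a single gene
#'
#' @param name Unique gene identifier.
#' @param kind `"boolean"` (domain 0/1), `"ordered"` (sorted numeric domain,
#'   mutated by the window operator) or `"nominal"` (unordered labels,
#'   mutated by uniform redraw).
#' @param domain Allowed values; strictly sorted for ordered genes.
#' @param group Chromosome section: `part1` (feature mask), `part2a` (CNN),
#'   `part2b` (LSTM), `part2c` (dense), `part2d` (training).
#' @return One-row tibble describing the gene.
#' @export
gene_spec <- function(name, kind, domain, group) {
  kind <- match.arg(kind, c("boolean", "ordered", "nominal"))
  group <- match.arg(group, c("part1", "part2a", "part2b", "part2c", "part2d"))
  assert_that(length(domain) >= 1, "gene domains must be non-empty")
  if (kind == "boolean") {
    domain <- c(0, 1)
  } else if (kind == "ordered") {
    domain <- as.numeric(domain)
    assert_that(!is.unsorted(domain, strictly = TRUE),
                "ordered domains must be strictly sorted")
  } else {
    domain <- as.character(domain)
  }
  tibble::tibble(name = name, kind = kind, group = group, domain = list(domain))
}

#' Construct a genome schema
#'
#' @param genes Tibble of [gene_spec()] rows, in chromosome order.
#' @param registry_names Feature names bound to the part-1 mask, in order.
#' @return A `genome_schema`; its length `n` defines the default per-gene
#'   mutation rate `2 / n`.
#' @export
genome_schema <- function(genes, registry_names) {
  assert_that(!anyDuplicated(genes$name), "gene names must be unique")
  p1 <- genes[genes$group == "part1", ]
  assert_that(all(p1$kind == "boolean"), "part1 genes must all be boolean")
  assert_that(nrow(p1) == length(registry_names),
              "part1 must hold exactly one boolean gene per registry feature")
  ord <- match(genes$group, c("part1", "part2a", "part2b", "part2c", "part2d"))
  assert_that(!is.unsorted(ord), "gene groups must appear in order part1, 2a, 2b, 2c, 2d")
  structure(list(genes = genes, registry_names = registry_names),
            class = "genome_schema")
}

#' @export
length.genome_schema <- function(x) nrow(x$genes)

#' @export
print.genome_schema <- function(x, ...) {
  cat(sprintf("<genome_schema> %d genes (%s)\n", length(x),
              paste(sprintf("%s: %d", names(table(x$genes$group)),
                            as.integer(table(x$genes$group))), collapse = ", ")))
  invisible(x)
}

#' Default genome schema over a feature registry
#'
#' One boolean selection gene per registry feature (part 1), then grouped
#' hyperparameter genes: a convolution-depth gene (1-5) with five slots of
#' filters/kernel/pool genes (part 2a), an LSTM-depth gene (1-3) with three
#' unit slots (part 2b), a dense-depth gene (1-2) with two unit/dropout
#' slots (part 2c), and training genes — learning rate, batch size, epochs,
#' optimizer, activation (part 2d). Slot genes beyond the active depth are
#' carried in the chromosome but ignored when decoding, which keeps the
#' chromosome length fixed so two-point crossover stays well-defined.
#'
#' @param registry A [build_registry()] result (or any `feature_registry`).
#' @return A `genome_schema`.
#' @export
#' @examples
#' length(make_default_schema(build_registry()))
make_default_schema <- function(registry = build_registry()) {
  genes <- list()
  for (nm in registry$name) {
    genes[[length(genes) + 1]] <- gene_spec(paste0("sel_", nm), "boolean",
                                            c(0, 1), "part1")
  }
  genes[[length(genes) + 1]] <- gene_spec("conv_depth", "ordered", 1:5, "part2a")
  for (i in 1:5) {
    genes[[length(genes) + 1]] <- gene_spec(paste0("conv", i, "_filters"),
                                            "ordered", c(8, 16, 32, 64), "part2a")
    genes[[length(genes) + 1]] <- gene_spec(paste0("conv", i, "_kernel"),
                                            "ordered", c(3, 5, 7, 11), "part2a")
    genes[[length(genes) + 1]] <- gene_spec(paste0("conv", i, "_pool"),
                                            "ordered", c(2, 4), "part2a")
  }
  genes[[length(genes) + 1]] <- gene_spec("lstm_depth", "ordered", 1:3, "part2b")
  for (i in 1:3) {
    genes[[length(genes) + 1]] <- gene_spec(paste0("lstm", i, "_units"),
                                            "ordered", c(16, 32, 64, 128), "part2b")
  }
  genes[[length(genes) + 1]] <- gene_spec("dense_depth", "ordered", 1:2, "part2c")
  for (i in 1:2) {
    genes[[length(genes) + 1]] <- gene_spec(paste0("dense", i, "_units"),
                                            "ordered", c(16, 32, 64, 128), "part2c")
    genes[[length(genes) + 1]] <- gene_spec(paste0("dense", i, "_dropout"),
                                            "ordered", c(0, 0.2, 0.4), "part2c")
  }
  genes[[length(genes) + 1]] <- gene_spec("learning_rate", "ordered",
                                          c(1e-4, 3e-4, 1e-3, 3e-3), "part2d")
  genes[[length(genes) + 1]] <- gene_spec("batch_size", "ordered",
                                          c(8, 16, 32), "part2d")
  genes[[length(genes) + 1]] <- gene_spec("epochs", "ordered",
                                          c(5, 10, 15), "part2d")
  genes[[length(genes) + 1]] <- gene_spec("optimizer", "nominal",
                                          c("adam", "rmsprop", "sgd"), "part2d")
  genes[[length(genes) + 1]] <- gene_spec("activation", "nominal",
                                          c("relu", "tanh", "elu"), "part2d")
  genome_schema(dplyr::bind_rows(genes), registry$name)
}

#' Draw a random chromosome
#'
#' Each gene value is drawn uniformly and independently from its domain.
#' Consumes the current random stream.
#'
#' @param schema A [genome_schema()].
#' @return A `chromosome`: named list of gene values.
#' @export
random_chromosome <- function(schema) {
  vals <- purrr::map(schema$genes$domain, sample_from)
  structure(setNames(vals, schema$genes$name), class = "chromosome")
}

#' Validate a chromosome against its schema
#'
#' @param chromosome A chromosome (named list of gene values).
#' @param schema The [genome_schema()] it must conform to.
#' @return `TRUE` invisibly; otherwise an error naming the offending gene.
#' @export
validate_chromosome <- function(chromosome, schema) {
  assert_that(length(chromosome) == length(schema),
              "chromosome length does not match the schema")
  assert_that(identical(names(chromosome), schema$genes$name),
              "chromosome gene names do not match the schema")
  for (i in seq_len(length(schema))) {
    v <- chromosome[[i]]
    dom <- schema$genes$domain[[i]]
    if (length(v) != 1 || !v %in% dom) {
      abort(sprintf("gene '%s' has value outside its domain", schema$genes$name[i]),
            class = "comafusion_genome_error")
    }
  }
  invisible(TRUE)
}

#' Decode a chromosome into a feature mask and an architecture
#'
#' Part 1 becomes the binary feature mask verbatim. For each layer block,
#' only the first depth-gene-many slots are read; the remaining slot genes
#' are carried but ignored. Every schema-valid chromosome decodes to a valid
#' [architecture_spec()] by construction. Decoding is a pure function.
#'
#' @param chromosome A schema-valid chromosome.
#' @param schema Its [genome_schema()].
#' @return List with `mask` (named integer vector over the registry) and
#'   `spec` (an [architecture_spec()]).
#' @export
decode_chromosome <- function(chromosome, schema) {
  g <- function(nm) chromosome[[nm]]
  mask <- vapply(schema$registry_names,
                 function(nm) as.integer(g(paste0("sel_", nm))), integer(1))
  act <- g("activation")
  conv <- purrr::map(seq_len(g("conv_depth")), function(i) {
    list(filters = g(paste0("conv", i, "_filters")),
         kernel_size = g(paste0("conv", i, "_kernel")),
         pool_size = g(paste0("conv", i, "_pool")),
         activation = act)
  })
  lstm <- purrr::map(seq_len(g("lstm_depth")), function(i) {
    list(units = g(paste0("lstm", i, "_units")))
  })
  dense <- purrr::map(seq_len(g("dense_depth")), function(i) {
    list(units = g(paste0("dense", i, "_units")),
         dropout = g(paste0("dense", i, "_dropout")))
  })
  spec <- architecture_spec(
    conv_layers = conv, lstm_layers = lstm, dense_layers = dense,
    training = list(learning_rate = g("learning_rate"),
                    batch_size = g("batch_size"),
                    epochs = g("epochs"),
                    optimizer = g("optimizer")))
  list(mask = mask, spec = spec)
}

#' Serialize a genome schema (or chromosome) to JSON
#'
#' Schemas round-trip exactly: `read_genome_schema(write_genome_schema(s))`
#' reproduces `s`.
#'
#' @param schema A [genome_schema()].
#' @param path Output file.
#' @return `path` invisibly (writers); the object (readers).
#' @export
write_genome_schema <- function(schema, path) {
  payload <- list(
    registry_names = schema$registry_names,
    genes = purrr::pmap(schema$genes, function(name, kind, group, domain) {
      list(name = name, kind = kind, group = group, domain = as.list(domain))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genome_schema
#' @export
read_genome_schema <- function(path) {
  payload <- jsonlite::read_json(path)
  genes <- dplyr::bind_rows(purrr::map(payload$genes, function(gn) {
    gene_spec(gn$name, gn$kind, unlist(gn$domain), gn$group)
  }))
  genome_schema(genes, unlist(payload$registry_names))
}

#' @rdname write_genome_schema
#' @param chromosome A chromosome to dump / reload.
#' @export
write_chromosome <- function(chromosome, path) {
  jsonlite::write_json(unclass(chromosome), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genome_schema
#' @export
read_chromosome <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE), class = "chromosome")
}
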