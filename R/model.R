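#' Model specifications with a uniform flat-parameter interface
#'
#' The federated engine is model-agnostic: every model is a spec plus a
#' flat numeric parameter vector with a shape registry mapping named
#' blocks (GLM coefficients, embedding table, layer weights and biases) to
#' slices. Two families are provided: penalized binomial GLMs with logit
#' (odds-ratio) or log (risk-ratio) link, and an embedding feed-forward
#' network for bag-of-token EHR data.
#'
#' @param feature_names Ordered design-column names (GLM).
#' @param link `"logit"` or `"log"`.
#' @param l1,l2 L1 / L2 penalty magnitudes (>= 0); the loss is
#'   mean NLL `+ l1 * sum(|w|) + l2 * sum(w^2)` over penalized blocks.
#'   Intercepts and biases are never penalized.
#' @param intercept Include an intercept term (GLM).
#' @return An object of class `glm_spec` or `mlp_spec` (both inherit
#'   `model_spec`).
#' @export
glm_spec <- function(feature_names, link = c("logit", "log"),
                     l1 = 0, l2 = 0, intercept = TRUE) {
  link <- match.arg(link)
  stopifnot(is.character(feature_names), length(feature_names) >= 1L,
            l1 >= 0, l2 >= 0, is_flag(intercept))
  structure(list(kind = "glm", link = link,
                 feature_names = feature_names,
                 l1 = l1, l2 = l2, intercept = intercept),
            class = c("glm_spec", "model_spec"))
}

#' @rdname glm_spec
#' @param vocab_size Token vocabulary size; `0` means no embedding block
#'   and the network consumes `input_dim` numeric features directly (the
#'   "1 hidden layer on tabular covariates" configuration).
#' @param embedding_dim Embedding dimension (ignored when `vocab_size = 0`).
#' @param input_dim Input feature count when `vocab_size = 0`.
#' @param pooling `"sum"` or `"mean"` pooling of token embeddings.
#' @param hidden_sizes Hidden-layer widths, e.g. `c(512, 256, 128)`.
#' @param activation `"relu"` or `"tanh"`.
#' @export
mlp_spec <- function(vocab_size, embedding_dim = 16L, input_dim = NULL,
                     pooling = c("sum", "mean"),
                     hidden_sizes = c(512L, 256L, 128L),
                     activation = c("relu", "tanh"),
                     l1 = 0, l2 = 0) {
  pooling <- match.arg(pooling)
  activation <- match.arg(activation)
  stopifnot(is_count(vocab_size, min = 0), length(hidden_sizes) >= 1L,
            all(hidden_sizes >= 1), l1 >= 0, l2 >= 0)
  if (vocab_size == 0L) {
    if (is.null(input_dim) || !is_count(input_dim)) {
      stopf("vocab_size = 0 requires input_dim >= 1")
    }
    d_in <- as.integer(input_dim)
  } else {
    if (!is_count(embedding_dim)) stopf("embedding_dim must be >= 1")
    d_in <- as.integer(embedding_dim)
  }
  structure(list(kind = "mlp", vocab_size = as.integer(vocab_size),
                 embedding_dim = as.integer(embedding_dim),
                 input_dim = d_in, pooling = pooling,
                 hidden_sizes = as.integer(hidden_sizes),
                 activation = activation, l1 = l1, l2 = l2),
            class = c("mlp_spec", "model_spec"))
}

# ---- shape registry ---------------------------------------------------

# Blocks: list(name, nrow, ncol, penalized); flat layout is column-major
# concatenation in registry order.
shape_registry <- function(spec) {
  if (spec$kind == "glm") {
    blocks <- list()
    if (spec$intercept) {
      blocks[[length(blocks) + 1L]] <-
        list(name = "(Intercept)", nrow = 1L, ncol = 1L, penalized = FALSE)
    }
    blocks[[length(blocks) + 1L]] <-
      list(name = "coef", nrow = length(spec$feature_names), ncol = 1L,
           penalized = TRUE)
    return(blocks)
  }
  blocks <- list()
  if (spec$vocab_size > 0L) {
    blocks[[1L]] <- list(name = "embedding", nrow = spec$vocab_size,
                         ncol = spec$embedding_dim, penalized = TRUE)
  }
  dims <- c(spec$input_dim, spec$hidden_sizes, 1L)
  for (i in seq_len(length(dims) - 1L)) {
    blocks[[length(blocks) + 1L]] <-
      list(name = paste0("W", i), nrow = dims[i], ncol = dims[i + 1L],
           penalized = TRUE)
    blocks[[length(blocks) + 1L]] <-
      list(name = paste0("b", i), nrow = 1L, ncol = dims[i + 1L],
           penalized = FALSE)
  }
  blocks
}

registry_sizes <- function(registry) {
  vapply(registry, function(b) b$nrow * b$ncol, numeric(1))
}

#' Total number of trainable parameters of a model spec
#'
#' @param spec A `glm_spec` or `mlp_spec`.
#' @return Integer parameter count (sum of all block sizes).
#' @examples
#' count_params(glm_spec(paste0("x", 1:12)))  # 13
#' @export
count_params <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  as.integer(sum(registry_sizes(shape_registry(spec))))
}

# Offsets of each block in the flat vector.
registry_offsets <- function(registry) {
  sz <- registry_sizes(registry)
  off <- cumsum(c(0, sz[-length(sz)]))
  stats::setNames(off, vapply(registry, `[[`, "", "name"))
}

#' Initialize a flat parameter vector for a model spec
#'
#' GLMs start at zero; networks use uniform Glorot initialization for
#' weight matrices and the embedding, zeros for biases.
#'
#' @param spec A `model_spec`.
#' @param seed RNG seed for network initialization.
#' @return An object of class `model_params`: `values` (flat numeric
#'   vector) plus the shape registry.
#' @export
init_params <- function(spec, seed = 1L) {
  registry <- shape_registry(spec)
  n <- sum(registry_sizes(registry))
  if (spec$kind == "glm") {
    values <- numeric(n)
  } else {
    values <- with_seed(seed, {
      unlist(lapply(registry, function(b) {
        if (!b$penalized) return(numeric(b$nrow * b$ncol))  # biases
        s <- sqrt(6 / (b$nrow + b$ncol))
        stats::runif(b$nrow * b$ncol, -s, s)
      }), use.names = FALSE)
    })
  }
  new_params(values, registry)
}

new_params <- function(values, registry) {
  structure(list(values = as.numeric(values), registry = registry),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("model_params: %d values in %d blocks (%s)\n",
              length(x$values), length(x$registry),
              paste(vapply(x$registry, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

#' Extract a named block from a flat parameter vector
#'
#' @param params A `model_params`.
#' @param name Block name (e.g. `"coef"`, `"embedding"`, `"W1"`).
#' @return The block as a matrix (or vector for 1-column blocks).
#' @export
param_block <- function(params, name) {
  registry <- params$registry
  nms <- vapply(registry, `[[`, "", "name")
  i <- match(name, nms)
  if (is.na(i)) stopf("no parameter block '%s'", name)
  b <- registry[[i]]
  off <- registry_offsets(registry)[[name]]
  v <- params$values[(off + 1L):(off + b$nrow * b$ncol)]
  if (b$ncol == 1L) v else matrix(v, b$nrow, b$ncol)
}

# Logical mask of penalized entries in the flat vector.
penalty_mask <- function(registry) {
  unlist(lapply(registry, function(b) rep(b$penalized, b$nrow * b$ncol)),
         use.names = FALSE)
}

#' Serialize / restore model parameters as JSON
#'
#' Round-trippable checkpoint format: the flat value vector together with
#' the shape registry.
#'
#' @param params A `model_params`.
#' @param path Output JSON path.
#' @return `write_params()` returns `path` invisibly; `read_params()` the
#'   restored `model_params`.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(
    list(values = params$values,
         registry = lapply(params$registry, function(b) {
           list(name = b$name, nrow = b$nrow, ncol = b$ncol,
                penalized = b$penalized)
         })),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  js <- jsonlite::read_json(path)
  registry <- lapply(js$registry, function(b) {
    list(name = b$name, nrow = as.integer(b$nrow), ncol = as.integer(b$ncol),
         penalized = isTRUE(b$penalized))
  })
  new_params(unlist(js$values), registry)
}
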