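#' Write / read a mixture model as a JSON document
#'
#' Serializes the mixture weights, feature metadata and all component
#' parameters (including CSI structure or tree topologies) to a compact
#' JSON document that round-trips through [read_model()].  Component and
#' feature indices in the document are 0-based.
#'
#' @param model A `mixture_model`, `csi_mixture` or `dtree_mixture`.
#' @param path Output path.
#' @param feature_names Optional feature names stored in the document.
#' @return Invisibly, the path.
#' @export
write_model <- function(model, path, feature_names = NULL) {
  doc <- model_to_list(model, feature_names)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

model_to_list <- function(model, feature_names = NULL) {
  domains <- model_domains(model)
  p <- length(domains)
  feature_names <- feature_names %||% paste0("f", seq_len(p))
  features <- lapply(seq_len(p), function(j) {
    d <- domains[[j]]
    if (d$type == "discrete") {
      list(name = feature_names[j], type = "discrete", alphabet = d$alphabet)
    } else {
      list(name = feature_names[j], type = "continuous")
    }
  })
  base <- list(format = "heteromix-model", version = 1L,
               family = model_family(model), K = model$K, pi = model$pi,
               features = features)
  if (inherits(model, "csi_mixture")) {
    st <- model$structure
    base$structure <- list(
      groups = lapply(st$groups, function(gj) lapply(gj, function(b) b - 1L)),
      params = lapply(st$params, function(pj) lapply(pj, dist_to_list)))
  } else if (inherits(model, "dtree_mixture")) {
    base$components <- lapply(model$components, function(comp) {
      pa <- as.list(comp$topology$parent - 1L)
      pa[is.na(comp$topology$parent)] <- list(NULL)
      list(root = comp$topology$root - 1L, parent = pa,
           root_dist = dist_to_list(comp$root_dist),
           edges = lapply(comp$edge_dists, function(e) {
             if (is.null(e)) NULL else dist_to_list(e)
           }))
    })
  } else {
    base$components <- lapply(model$components, function(comp) {
      list(dists = lapply(comp$dists, dist_to_list))
    })
  }
  base
}

model_family <- function(model) {
  if (inherits(model, "csi_mixture")) "csi"
  else if (inherits(model, "dtree_mixture")) "dtree"
  else "product"
}

dist_to_list <- function(d) {
  if (inherits(d, "gaussian_dist")) {
    list(type = "gaussian", mean = d$mean, sd = d$sd)
  } else if (inherits(d, "discrete_dist")) {
    list(type = "discrete", alphabet = d$alphabet, probs = d$probs)
  } else if (inherits(d, "exponential_dist")) {
    list(type = "exponential", rate = d$rate)
  } else if (inherits(d, "cond_gaussian")) {
    list(type = "cond_gaussian", intercept = d$intercept, slope = d$slope,
         sd = d$sd)
  } else if (inherits(d, "cond_discrete")) {
    list(type = "cond_discrete", parent_alphabet = d$parent_alphabet,
         child_alphabet = d$child_alphabet,
         table = apply(d$table, 1L, function(r) r, simplify = FALSE))
  } else {
    stop("cannot serialize distribution of class ", class(d)[1L])
  }
}

dist_from_list <- function(x) {
  switch(x$type,
    gaussian = dist_gaussian(x$mean, x$sd),
    discrete = dist_discrete(unlist(x$alphabet), unlist(x$probs)),
    exponential = dist_exponential(x$rate),
    cond_gaussian = cond_gaussian(x$intercept, x$slope, x$sd),
    cond_discrete = cond_discrete(unlist(x$parent_alphabet),
                                  unlist(x$child_alphabet),
                                  do.call(rbind, lapply(x$table, unlist))),
    stop("unknown distribution type in model document: ", x$type))
}

#' @rdname write_model
#' @return `read_model`: the reconstructed model, with the stored feature
#'   names in `attr(, "feature_names")`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "heteromix-model")) {
    stop("not a heteromix model document: ", path)
  }
  pi <- unlist(doc$pi)
  feats <- doc$features
  feature_names <- vapply(feats, function(f) f$name, character(1))
  domains <- lapply(feats, function(f) {
    if (f$type == "discrete") {
      list(type = "discrete", alphabet = unlist(f$alphabet))
    } else {
      list(type = "continuous")
    }
  })
  model <- switch(doc$family,
    product = mixture_model(pi, lapply(doc$components, function(c) {
      product_component(lapply(c$dists, dist_from_list))
    })),
    csi = {
      groups <- lapply(doc$structure$groups, function(gj) {
        lapply(gj, function(b) unlist(b) + 1L)
      })
      params <- lapply(doc$structure$params, function(pj) {
        lapply(pj, dist_from_list)
      })
      csi_mixture(pi, csi_structure(groups, params))
    },
    dtree = {
      comps <- lapply(doc$components, function(c) {
        parent <- vapply(c$parent, function(v) {
          if (is.null(v)) NA_integer_ else as.integer(v) + 1L
        }, integer(1))
        edges <- lapply(c$edges, function(e) {
          if (is.null(e)) NULL else dist_from_list(e)
        })
        dtree_component(tree_topology(parent, as.integer(c$root) + 1L),
                        dist_from_list(c$root_dist), edges)
      })
      dtree_mixture(pi, comps, domains)
    },
    stop("unknown model family: ", doc$family))
  attr(model, "feature_names") <- feature_names
  model
}
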