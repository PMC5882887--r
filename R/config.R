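# Structured config documents for models and gains: JSON with explicit
# matrix shape fields (row-major data), schema-versioned, validated on
# load, and bit-exact on round-trip (doubles written with 17 significant
# digits).

.mat_to_doc <- function(m) {
  m <- as.matrix(m)
  list(rows = nrow(m), cols = ncol(m),
       data = as.numeric(t(m)))  # row-major
}

.doc_to_mat <- function(d, what) {
  if (is.null(d$rows) || is.null(d$cols) || is.null(d$data) ||
      length(d$data) != d$rows * d$cols) {
    stop(sprintf("malformed matrix entry '%s' in config", what),
         call. = FALSE)
  }
  matrix(as.numeric(d$data), nrow = d$rows, ncol = d$cols, byrow = TRUE)
}

.kernel_to_doc <- function(k) {
  if (k$type == "exponential") list(type = "exponential", rate = k$rate)
  else list(type = "finite", weights = k$weights)
}

.doc_to_kernel <- function(d) {
  if (identical(d$type, "exponential")) {
    exponential_kernel(as.numeric(d$rate))
  } else {
    finite_kernel(as.numeric(d$weights))
  }
}

#' Write a GRN model as a structured config document
#'
#' Serializes every model parameter to JSON with explicit shape fields
#' (matrices row-major) and a schema version. Doubles are written with 17
#' significant digits so the round-trip through [read_grn_config()] is
#' bit-exact.
#'
#' @param model a [grn_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grn_config <- function(model, path) {
  stopifnot(inherits(model, "grn_model"))
  doc <- list(
    schema = "grnest-model/1",
    n = model$n, l = model$l,
    matrices = lapply(model[c("A", "B", "C", "D", "E", "F", "H",
                              "L_x", "L_y", "M", "N", "sigma")],
                      .mat_to_doc),
    delays = list(rho1 = model$rho1, rho2 = model$rho2,
                  delta_m = model$delta_m, delta_M = model$delta_M,
                  tau_m = model$tau_m, tau_M = model$tau_M),
    kernels = list(mu = .kernel_to_doc(model$mu_kernel),
                   xi = .kernel_to_doc(model$xi_kernel)),
    dropout = list(alpha0 = model$alpha0, beta0 = model$beta0),
    hill = model$hill)
  if (!is.null(model$uncertainty)) {
    doc$uncertainty <- lapply(
      model$uncertainty[c("R", paste0("W", 1:6))], .mat_to_doc)
  }
  if (length(model$extras)) {
    doc$extras <- lapply(model$extras, function(x) {
      if (is.matrix(x)) .mat_to_doc(x) else x
    })
  }
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' Read a GRN model from a structured config document
#'
#' @param path path to a document written by [write_grn_config()].
#' @return a [grn_model()].
#' @export
read_grn_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "grnest-model/1")) {
    stop("unrecognized config schema: ", doc$schema %||% "<missing>",
         call. = FALSE)
  }
  M <- lapply(names(doc$matrices), function(nm) {
    .doc_to_mat(doc$matrices[[nm]], nm)
  })
  names(M) <- names(doc$matrices)
  unc <- NULL
  if (!is.null(doc$uncertainty)) {
    u <- lapply(names(doc$uncertainty), function(nm) {
      .doc_to_mat(doc$uncertainty[[nm]], nm)
    })
    names(u) <- names(doc$uncertainty)
    unc <- uncertainty_structure(R = u$R, W1 = u$W1, W2 = u$W2, W3 = u$W3,
                                 W4 = u$W4, W5 = u$W5, W6 = u$W6)
  }
  extras <- list()
  if (!is.null(doc$extras)) {
    extras <- lapply(doc$extras, function(x) {
      if (is.list(x) && !is.null(x$rows)) .doc_to_mat(x, "extra") else x
    })
  }
  grn_model(
    A = M$A, B = M$B, C = M$C, D = M$D, E = M$E, F = M$F, H = M$H,
    L_x = M$L_x, L_y = M$L_y, M = M$M, N = M$N,
    rho1 = doc$delays$rho1, rho2 = doc$delays$rho2,
    delta_m = doc$delays$delta_m, delta_M = doc$delays$delta_M,
    tau_m = doc$delays$tau_m, tau_M = doc$delays$tau_M,
    mu_kernel = .doc_to_kernel(doc$kernels$mu),
    xi_kernel = .doc_to_kernel(doc$kernels$xi),
    alpha0 = as.numeric(doc$dropout$alpha0),
    beta0 = as.numeric(doc$dropout$beta0),
    hill = as.numeric(doc$hill),
    uncertainty = unc, sigma = M$sigma, extras = extras)
}

#' Write / read estimator gains
#'
#' Gains use the same structured-document format as models.
#'
#' @param gains a [grn_gains()] record.
#' @param path file path.
#' @return `path` invisibly (write) or a `grn_gains` (read).
#' @export
write_grn_gains <- function(gains, path) {
  stopifnot(inherits(gains, "grn_gains"))
  doc <- list(schema = "grnest-gains/1",
              matrices = lapply(gains[c("A_x", "B_x", "A_y", "B_y")],
                                .mat_to_doc))
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_grn_gains
#' @export
read_grn_gains <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "grnest-gains/1")) {
    stop("unrecognized gains schema", call. = FALSE)
  }
  g <- lapply(names(doc$matrices), function(nm) {
    .doc_to_mat(doc$matrices[[nm]], nm)
  })
  names(g) <- names(doc$matrices)
  grn_gains(A_x = g$A_x, B_x = g$B_x, A_y = g$A_y, B_y = g$B_y)
}
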