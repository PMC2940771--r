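#' Read or write a network parameter config file
#'
#' One network per YAML document. Field names mirror the model symbols:
#' `mechanism`, `a1`, `b1`, `a2`, `b2`, `d1x`, `d1y` (or a single `d1`),
#' `d2x`, `d2y`, `n`, `m`, `eps_X`, `eps_Y`, `eps_g`, `k_leak`, `D_in`,
#' `D_out`, `x0`, `y0`. Activation kinds may be given explicitly as
#' `activation_x` / `activation_y` (`"linear"` or `"hill"`); otherwise a
#' branch is Hill whenever its exponent (`n` or `m`) is present, linear
#' otherwise.
#'
#' @param path file path.
#' @param params a [network_parameters()] object (for writing).
#' @return `read_network_config()` returns a [network_parameters()] object;
#'   `write_network_config()` returns `path` invisibly. A config written by
#'   the package re-parses to an identical parameter set.
#' @export
read_network_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$mechanism))
    stop("config is missing required field `mechanism`", call. = FALSE)
  num <- function(nm, default = NULL) {
    v <- cfg[[nm]]
    if (is.null(v)) return(default)
    if (!is.numeric(v)) stop(sprintf("config field `%s` must be numeric", nm),
                             call. = FALSE)
    v
  }
  act <- function(kind_field, exp_field, eps_field) {
    kind <- cfg[[kind_field]]
    expn <- num(exp_field)
    if (is.null(kind)) kind <- if (is.null(expn)) "linear" else "hill"
    if (kind == "linear") return(linear_activation())
    if (kind != "hill")
      stop(sprintf("config field `%s` must be 'linear' or 'hill'", kind_field),
           call. = FALSE)
    if (is.null(expn))
      stop(sprintf("hill activation requires `%s`", exp_field), call. = FALSE)
    eps <- num(eps_field)
    if (is.null(eps))
      stop(sprintf("hill activation requires `%s`", eps_field), call. = FALSE)
    hill_activation(exponent = expn, threshold = eps)
  }
  d1 <- num("d1", 1)
  network_parameters(mechanism = cfg$mechanism,
                     a1 = num("a1"), b1 = num("b1"),
                     a2 = num("a2", 1), b2 = num("b2", 1),
                     d1x = num("d1x", d1), d1y = num("d1y", d1),
                     d2x = num("d2x", 1), d2y = num("d2y", 1),
                     fX = act("activation_x", "n", "eps_X"),
                     fY = act("activation_y", "m", "eps_Y"),
                     x0 = num("x0", 1), y0 = num("y0", 1),
                     eps_g = num("eps_g"), k_leak = num("k_leak"),
                     D_in = num("D_in"), D_out = num("D_out"))
}

#' @rdname read_network_config
#' @export
write_network_config <- function(params, path) {
  stopifnot(inherits(params, "sigspec_network"))
  cfg <- list(mechanism = params$mechanism,
              a1 = params$a1, b1 = params$b1,
              a2 = params$a2, b2 = params$b2,
              d1x = params$d1x, d1y = params$d1y,
              d2x = params$d2x, d2y = params$d2y,
              x0 = params$x0, y0 = params$y0,
              activation_x = params$fX$kind,
              activation_y = params$fY$kind)
  if (params$fX$kind == "hill") {
    cfg$n <- params$fX$exponent
    cfg$eps_X <- params$fX$threshold
  }
  if (params$fY$kind == "hill") {
    cfg$m <- params$fY$exponent
    cfg$eps_Y <- params$fY$threshold
  }
  if (params$fX$kind == "custom" || params$fY$kind == "custom")
    stop("custom activation functions cannot be serialized to a config file",
         call. = FALSE)
  cfg$eps_g <- params$eps_g
  cfg$k_leak <- params$k_leak
  cfg$D_in <- params$D_in
  cfg$D_out <- params$D_out
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}
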