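#' Plain-text model and run configuration
#'
#' Models, regions and run settings can be described in a YAML file so that
#' command-line runs and library runs share one input. The schema:
#'
#' ```yaml
#' model:
#'   species: [S1, S2]
#'   params: {alpha: 0.05, beta: 0.01, P: 6, nh: 2, K: 10}
#'   reactions:
#'     - {type: hill-repression, delta: [1, 0], vmax: alpha*P,
#'        repressor: S2, K: K, nh: nh, label: S1 production}
#'     - {type: mass-action, delta: [-1, 0], k: beta, species: S1}
#'     - {type: constant, delta: [0, 1], rate: 0.05}
#' region:
#'   box:
#'     S1: [alpha/(3*beta)*P, 2*alpha/beta*P]
#'     S2: [0, P]
#' initial:            # one of:
#'   point: {S1: 30, S2: 0}
#'   # qsd: true
#' times: [21600, 43200, 86400]
#' eps: 1.0e-6
#' max_loops: 100000
#' qsd_method: restriction
#' ```
#'
#' Rate and bound entries may be numbers or arithmetic expressions over the
#' names in `params`. Three declarative rate families are supported:
#' `constant` (`rate`), `mass-action` (`k * count(species)`), and
#' `hill-repression` (`vmax / (1 + (count(repressor)/K)^nh)`).
#'
#' @param path YAML file path.
#' @return `read_run_config()`: list with `net`, `region`, `initial`
#'   (list: `kind` = "point"/"qsd", `state`), `times`, `eps`, `max_loops`,
#'   `qsd_method`, `raw` (the parsed YAML).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("config lacks a `model` block")
  net <- model_from_config(cfg$model)
  if (is.null(cfg$region)) stop("config lacks a `region` block")
  region <- region_from_config(cfg$region, net)
  initial <- initial_from_config(cfg$initial, net)
  list(net = net, region = region, initial = initial,
       times = as.numeric(cfg$times %||% c(21600, 43200, 86400)),
       eps = as.numeric(cfg$eps %||% 1e-6),
       max_loops = as.integer(cfg$max_loops %||% 1e5),
       qsd_method = cfg$qsd_method %||% "restriction",
       raw = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

eval_param <- function(x, params) {
  if (is.numeric(x)) return(x)
  v <- eval(parse(text = as.character(x)),
            envir = as.list(params), enclos = baseenv())
  if (!is.numeric(v) || length(v) != 1L)
    stop("expression '", x, "' did not evaluate to a number")
  v
}

#' @rdname read_run_config
#' @param model parsed `model` block (list).
#' @export
model_from_config <- function(model) {
  species <- as.character(model$species)
  params <- unlist(model$params) %||% numeric()
  reactions <- lapply(model$reactions, function(r) {
    delta <- as.integer(unlist(r$delta))
    lab <- r$label %||% r$type
    switch(
      r$type,
      "constant" = {
        rate <- eval_param(r$rate, params)
        if (rate < 0) stop("negative constant rate")
        reaction(delta, make_constant_rate(rate, delta),
                 type = "constant", type_params = list(rate = rate),
                 label = lab)
      },
      "mass-action" = {
        k <- eval_param(r$k, params)
        if (k < 0) stop("negative mass-action constant")
        si <- match(r$species, species)
        if (is.na(si)) stop("unknown species '", r$species, "'")
        reaction(delta, mass_action_decay_rate(k, si),
                 type = "mass-action",
                 type_params = list(k = k, species = r$species), label = lab)
      },
      "hill-repression" = {
        vmax <- eval_param(r$vmax, params)
        K <- eval_param(r$K %||% 10, params)
        nh <- eval_param(r$nh, params)
        if (vmax < 0 || K <= 0 || nh < 1)
          stop("invalid hill-repression parameters")
        ri <- match(r$repressor, species)
        if (is.na(ri)) stop("unknown repressor '", r$repressor, "'")
        reaction(delta, hill_repression_rate(vmax, K, nh, ri),
                 type = "hill-repression",
                 type_params = list(vmax = vmax, K = K, nh = nh,
                                    repressor = r$repressor), label = lab)
      },
      stop("unknown reaction type '", r$type, "'")
    )
  })
  bcrn(species, reactions, params)
}

# a constant-rate reaction still must not drive counts negative
make_constant_rate <- function(rate, delta) {
  force(rate); force(delta)
  function(x) if (any(x + delta < 0)) 0 else rate
}

#' @rdname read_run_config
#' @param region parsed `region` block.
#' @param net the model, for species order and params.
#' @export
region_from_config <- function(region, net) {
  if (!is.null(region$box)) {
    sp <- net$species
    lo <- numeric(length(sp)); hi <- numeric(length(sp))
    for (i in seq_along(sp)) {
      b <- region$box[[sp[i]]]
      if (is.null(b) || length(b) != 2L)
        stop("region box needs a [lo, hi] pair for species '", sp[i], "'")
      lo[i] <- eval_param(b[[1]], net$params)
      hi[i] <- eval_param(b[[2]], net$params)
    }
    region_box(lo, hi)
  } else if (!is.null(region$states)) {
    region_states(do.call(rbind, lapply(region$states, unlist)))
  } else stop("region block needs `box` or `states`")
}

initial_from_config <- function(initial, net) {
  if (is.null(initial)) stop("config lacks an `initial` block")
  if (isTRUE(initial$qsd)) return(list(kind = "qsd", state = NULL))
  if (!is.null(initial$point)) {
    x <- vapply(net$species, function(s) {
      v <- initial$point[[s]]
      if (is.null(v)) stop("initial point lacks species '", s, "'")
      as.numeric(v)
    }, numeric(1))
    return(list(kind = "point", state = unname(x)))
  }
  stop("initial block needs `point` or `qsd: true`")
}

#' Serialise a model (and optional region) to the YAML schema
#'
#' Only models built from the declarative rate families (`constant`,
#' `mass-action`, `hill-repression`) can be serialised; custom rate
#' functions have no declarative record.
#'
#' @param net a [bcrn()].
#' @param path output file.
#' @param region optional [region_box()].
#' @param initial optional state vector for a point-mass initial block.
#' @export
write_model_config <- function(net, path, region = NULL, initial = NULL) {
  rx <- lapply(net$reactions, function(r) {
    if (r$type == "custom")
      stop("reaction '", r$label, "' has no declarative record; ",
           "custom rate laws cannot be serialised")
    c(list(type = r$type, delta = as.list(r$delta)),
      r$type_params, list(label = r$label))
  })
  cfg <- list(model = list(species = as.list(net$species),
                           params = as.list(net$params),
                           reactions = rx))
  if (!is.null(region)) {
    if (region$kind != "box") stop("only box regions are serialised")
    box <- list()
    for (i in seq_along(net$species))
      box[[net$species[i]]] <- list(region$lo[i], region$hi[i])
    cfg$region <- list(box = box)
  }
  if (!is.null(initial)) {
    pt <- as.list(as.numeric(initial))
    names(pt) <- net$species
    cfg$initial <- list(point = pt)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
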