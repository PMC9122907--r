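#' Architecture configuration for the lightweight attention U-Net family
#'
#' Declaratively describes one member of the model family: a four-level
#' encoder/decoder with two convolution blocks (3x3 conv + batch
#' normalisation + ReLU) per level, optional bounded channel attention after
#' every level, and an optional channel-narrowing midblock at the bottleneck.
#'
#' Channel widths follow one of two policies. Under `"doubling"` the encoder
#' widths double per level from `base_width` (64, 128, 256, 512); the
#' bottleneck doubles once more to 1024 unless add-skips force it to stay at
#' the deepest encoder width; decoder convolutions narrow to the width of the
#' next-shallower encoder level. Under `"fixed"` every convolution uses
#' `base_width` filters. Upsampling is either a learned 3x3 stride-2
#' transposed convolution (filters matching the mirrored encoder level) or
#' parameter-free nearest-neighbour upsampling. Skips are merged by channel
#' concatenation or element-wise addition. The output head is a 3x3
#' convolution to `output_channels` logistic channels.
#'
#' The midblock ("bottleneck narrowing with attention") applies a
#' convolution at the bottleneck width followed by successive
#' channel-halving convolutions down to `midblock_min_channels`, each
#' followed by an attention block, then restores the original width, adds a
#' skip from the midblock input, and applies a final attention block.
#' Midblock convolutions carry biases but no batch normalisation.
#'
#' @param input_size integer length-2, image height and width in pixels;
#'   both must be divisible by `2^depth`.
#' @param input_channels number of image channels (3 for RGB replicated
#'   grayscale).
#' @param width_policy `"doubling"` or `"fixed"`.
#' @param base_width base (doubling) or constant (fixed) number of filters;
#'   must be a power of two.
#' @param depth number of pooling levels.
#' @param attention enable channel attention blocks.
#' @param bottleneck_attention place an attention block after the bottleneck
#'   convolutions. The default (`NULL`) follows the family convention:
#'   present for fixed-width and transposed-convolution models, absent for
#'   doubling-width upsampling models.
#' @param skip_mode `"concatenate"` or `"add"`.
#' @param up_mode `"transpose"` or `"upsample"`.
#' @param midblock_min_channels narrowest midblock width (e.g. 16), or
#'   `NULL` for no midblock. Requires `attention = TRUE`; must be a power of
#'   two dividing `base_width`.
#' @param dropout_rate dropout fraction applied after each pooling and
#'   upsampling step.
#' @param output_channels number of logistic output channels.
#'
#' @return An object of class `faz_arch` (a validated list).
#' @seealso [build_model()], [arch_presets()]
#' @export
arch_config <- function(input_size = c(320L, 320L),
                        input_channels = 3L,
                        width_policy = c("doubling", "fixed"),
                        base_width = 64L,
                        depth = 4L,
                        attention = TRUE,
                        bottleneck_attention = NULL,
                        skip_mode = c("concatenate", "add"),
                        up_mode = c("transpose", "upsample"),
                        midblock_min_channels = NULL,
                        dropout_rate = 0.2,
                        output_channels = 3L) {
  width_policy <- match.arg(width_policy)
  skip_mode <- match.arg(skip_mode)
  up_mode <- match.arg(up_mode)
  input_size <- as.integer(rep_len(input_size, 2L))
  base_width <- as.integer(base_width)
  depth <- as.integer(depth)

  is_pow2 <- function(x) x >= 1 && bitwAnd(x, x - 1L) == 0L
  if (!is_pow2(base_width))
    stop("`base_width` must be a power of two, got ", base_width)
  if (any(input_size %% 2L^depth != 0L))
    stop("input height and width must be divisible by 2^depth = ", 2L^depth)
  if (!is.null(midblock_min_channels)) {
    midblock_min_channels <- as.integer(midblock_min_channels)
    if (!attention)
      stop("a narrowing midblock requires `attention = TRUE` ",
           "(it is narrowing of channels *with attention*)")
    if (!is_pow2(midblock_min_channels) ||
        midblock_min_channels > base_width ||
        base_width %% midblock_min_channels != 0L)
      stop("`midblock_min_channels` must be a power of two dividing the ",
           "bottleneck width (", base_width, ")")
  }
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must be in [0, 1)")
  if (is.null(bottleneck_attention))
    bottleneck_attention <- width_policy == "fixed" || up_mode == "transpose"

  structure(
    list(
      input_size = input_size,
      input_channels = as.integer(input_channels),
      width_policy = width_policy,
      base_width = base_width,
      depth = depth,
      attention = isTRUE(attention),
      bottleneck_attention = isTRUE(bottleneck_attention) && isTRUE(attention),
      skip_mode = skip_mode,
      up_mode = up_mode,
      midblock_min_channels = midblock_min_channels,
      dropout_rate = dropout_rate,
      output_channels = as.integer(output_channels)
    ),
    class = "faz_arch"
  )
}

# Channel plan implied by a configuration: encoder widths, bottleneck width,
# decoder conv widths, transpose-filter (mirror) widths, midblock widths.
arch_widths <- function(config) {
  d <- config$depth
  if (config$width_policy == "fixed") {
    enc <- rep(config$base_width, d)
    bott <- config$base_width
    dec <- rep(config$base_width, d)
  } else {
    enc <- config$base_width * 2L^(seq_len(d) - 1L)
    bott <- if (config$skip_mode == "add") enc[d] else 2L * enc[d]
    # decoder convs narrow to the next-shallower encoder width
    dec <- enc[pmax(seq(d - 1L, by = -1L, length.out = d), 1L)]
  }
  mid <- integer(0)
  if (!is.null(config$midblock_min_channels)) {
    w <- bott
    while (w > config$midblock_min_channels) {
      w <- w %/% 2L
      mid <- c(mid, w)
    }
  }
  list(encoder = enc, bottleneck = bott, decoder = dec,
       mirror = rev(enc), midblock = mid)
}

as_engine_config <- function(config) {
  w <- arch_widths(config)
  list(
    enc_widths = as.integer(w$encoder),
    bott_width = as.integer(w$bottleneck),
    dec_widths = as.integer(w$decoder),
    mirror_widths = as.integer(w$mirror),
    in_ch = config$input_channels,
    out_ch = config$output_channels,
    head_k = 3L,
    attention = config$attention,
    bottleneck_attention = config$bottleneck_attention,
    skip_add = config$skip_mode == "add",
    up_transpose = config$up_mode == "transpose",
    midblock = as.integer(w$midblock),
    dropout = config$dropout_rate
  )
}

#' Named architecture presets
#'
#' The seven members of the model family, from the conventional
#' transposed-convolution/concatenation U-Net to the lightweight
#' fixed-128-channel network with bottleneck channel narrowing
#' (`LWBNA_Unet`).
#'
#' @param input_size optional input size override (height, width).
#' @return A named list of [arch_config()] objects.
#' @export
arch_presets <- function(input_size = c(320L, 320L)) {
  cfg <- function(...) arch_config(input_size = input_size, ...)
  list(
    Unet = cfg(width_policy = "doubling", attention = FALSE,
               skip_mode = "concatenate", up_mode = "transpose"),
    Unet_AB = cfg(width_policy = "doubling", attention = TRUE,
                  skip_mode = "concatenate", up_mode = "transpose"),
    Unet_AB_Upsampling = cfg(width_policy = "doubling", attention = TRUE,
                             skip_mode = "concatenate", up_mode = "upsample"),
    Unet_AB_Upsampling_Add = cfg(width_policy = "doubling", attention = TRUE,
                                 skip_mode = "add", up_mode = "upsample"),
    Unet_AB_128_Upsampling_Add = cfg(width_policy = "fixed", base_width = 128L,
                                     attention = TRUE, skip_mode = "add",
                                     up_mode = "upsample"),
    Unet_AB_64_Upsampling_Add = cfg(width_policy = "fixed", base_width = 64L,
                                    attention = TRUE, skip_mode = "add",
                                    up_mode = "upsample"),
    LWBNA_Unet = cfg(width_policy = "fixed", base_width = 128L,
                     attention = TRUE, skip_mode = "add",
                     up_mode = "upsample", midblock_min_channels = 16L)
  )
}

#' Build a model from a configuration or preset name
#'
#' Instantiates the network with He-normal initial weights. Construction is
#' deterministic for a given `seed`.
#'
#' @param config an [arch_config()] object or one of the preset names from
#'   [arch_presets()].
#' @param input_size optional input-size override (applies to presets and
#'   configs alike).
#' @param seed integer seed for weight initialisation (and dropout noise
#'   during later training).
#' @return An object of class `faz_model`.
#' @examples
#' m <- build_model("LWBNA_Unet", input_size = c(64, 64))
#' count_parameters(m)
#' @export
build_model <- function(config, input_size = NULL, seed = 1L) {
  if (is.character(config)) {
    presets <- arch_presets()
    if (!config %in% names(presets))
      stop("unknown preset '", config, "'; valid presets: ",
           paste(names(presets), collapse = ", "))
    config <- presets[[config]]
  }
  if (!inherits(config, "faz_arch")) stop("`config` must be a faz_arch object or preset name")
  if (!is.null(input_size)) {
    config$input_size <- as.integer(rep_len(input_size, 2L))
    if (any(config$input_size %% 2L^config$depth != 0L))
      stop("input size must be divisible by 2^depth = ", 2L^config$depth)
  }
  ptr <- nn_build(as_engine_config(config), as.integer(seed))
  structure(list(config = config, ptr = ptr, seed = as.integer(seed)),
            class = "faz_model")
}

#' Total parameter count of a model
#'
#' Counts every weight in the network. By default the count includes the
#' non-trainable moving statistics of the batch-normalisation layers (two per
#' normalised channel), the convention used when reporting "total
#' parameters" for Keras-style models; set `include_stats = FALSE` for the
#' trainable count only.
#'
#' @param model a `faz_model` (or `faz_arch`, which is built temporarily).
#' @param include_stats include batch-normalisation moving statistics.
#' @return integer-valued numeric scalar.
#' @export
count_parameters <- function(model, include_stats = TRUE) {
  if (inherits(model, "faz_arch")) model <- build_model(model)
  stopifnot(inherits(model, "faz_model"))
  nn_param_count(model$ptr, include_stats)
}

#' @export
print.faz_model <- function(x, ...) {
  cfg <- x$config
  cat("<faz_model> ", cfg$width_policy, "-width U-Net",
      if (cfg$attention) " + attention", "\n", sep = "")
  cat("  input ", paste(cfg$input_size, collapse = "x"), "x",
      cfg$input_channels, ", skips: ", cfg$skip_mode, ", up: ", cfg$up_mode,
      if (!is.null(cfg$midblock_min_channels))
        paste0(", midblock down to ", cfg$midblock_min_channels, " channels"),
      "\n", sep = "")
  cat("  parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

#' @export
print.faz_arch <- function(x, ...) {
  w <- arch_widths(x)
  cat("<faz_arch> ", x$width_policy, " widths [",
      paste(w$encoder, collapse = ", "), "] | ", w$bottleneck, " | [",
      paste(w$decoder, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

# stack a list of H x W x C arrays (or one such array) into H x W x C x N
as_batch_array <- function(images, channels = NULL) {
  if (is.list(images)) {
    dims <- dim(images[[1]])
    if (length(dims) == 2L) dims <- c(dims, 1L)
    arr <- array(0, c(dims, length(images)))
    for (i in seq_along(images)) {
      im <- images[[i]]
      if (length(dim(im)) == 2L) dim(im) <- c(dim(im), 1L)
      arr[, , , i] <- im
    }
    images <- arr
  } else if (length(dim(images)) == 2L) {
    dim(images) <- c(dim(images), 1L, 1L)
  } else if (length(dim(images)) == 3L) {
    dim(images) <- c(dim(images), 1L)
  }
  if (!is.null(channels) && dim(images)[3] == 1L && channels > 1L)
    images <- images[, , rep(1L, channels), , drop = FALSE]
  images
}

#' Forward prediction
#'
#' Runs the network in inference mode (dropout disabled, batch normalisation
#' using its moving statistics) and returns per-pixel foreground
#' probabilities, averaged over the logistic output channels.
#'
#' @param object a `faz_model`.
#' @param images a single H x W x C array, an H x W x C x N array, or a list
#'   of H x W x C arrays, with values in \[0, 1\].
#' @param batch_size forward batch size.
#' @param ... unused.
#' @return An H x W x N array of probabilities in (0, 1); batch order is
#'   preserved.
#' @export
predict.faz_model <- function(object, images, batch_size = 8L, ...) {
  x <- as_batch_array(images, channels = object$config$input_channels)
  d <- dim(x)
  if (d[1] != object$config$input_size[1] || d[2] != object$config$input_size[2] ||
      d[3] != object$config$input_channels)
    stop("images must be ", object$config$input_size[1], "x",
         object$config$input_size[2], "x", object$config$input_channels,
         "; got ", paste(d[1:3], collapse = "x"))
  n <- d[4]
  out <- array(0, c(d[1], d[2], n))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    p <- nn_forward(object$ptr, x[, , , idx, drop = FALSE], FALSE)
    # channel-mean collapses the logistic channels to one probability map
    out[, , idx] <- apply(p, c(1, 2, 4), mean)
  }
  out
}

# weight access (used by serialization and the reference forward pass)
model_weights <- function(model) nn_get_weights(model$ptr)

set_model_weights <- function(model, weights) {
  nn_set_weights(model$ptr, weights)
  invisible(model)
}
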