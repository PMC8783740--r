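# swincount

Tree detection and counting in overhead RGB imagery with a shifted-window
transformer U-Net and density-map supervision.

## The problem

Plantation inventories (the motivating case is olive orchards imaged by
very-high-resolution satellites) need per-tree counts over areas far too
large to annotate manually. In overhead imagery a tree crown is a small
bright-tipped blob trailing a shadow; the difficulties are scale and
orientation variation, closely planted young trees whose crowns touch, and
bright non-tree objects that invite false detections.

`swincount` treats this as **density-map regression with point
supervision**: each tree is labelled by one center point (optionally
derived from a four-vertex box by its centroid, `(x̄, ȳ) = (¼Σxᵢ, ¼Σyᵢ)`),
the supervision target places a unit-mass Gaussian kernel at every point,
and the network regresses that map. The count estimate is the integral of
the predicted map; per-tree detections come from peak localisation on it.

## The model

A U-shaped encoder–decoder built entirely from windowed multi-head
self-attention:

* 4×4 patch partition (48-dim raw tokens) + linear embedding to C channels;
* four encoder stages at H/4 … H/32 with channels C, 2C, 4C, 8C, joined by
  2×2 patch merging;
* per-window attention `softmax(QKᵀ/√d + B) V` with a learned
  relative-position bias B, alternating plain (W-MSA) and shifted (SW-MSA,
  shift ⌊N/2⌋ with wrap-around masking) windows;
* a mirrored decoder with patch expanding and skip connections at H/16,
  H/8, H/4, and a 4× final expansion to a nonnegative density map at full
  resolution.

Evaluation uses the standard counting metrics, pooled over a test set:

    OA  = NE / NA × 100        (overall accuracy)
    OER = Nm / NA × 100        (omission error rate, missed trees)
    CER = Nf / NA × 100        (commission error rate, false detections)
    EE  = |NE − NA| / NA × 100 (estimation error)

Forward and backward passes are implemented in the package itself (R plus
a compiled attention kernel) — no external deep-learning runtime. A seeded
synthetic-orchard generator with exact ground truth makes the whole
pipeline testable end to end.

## Worked example

```r
library(swincount)

# 1. simulate an orchard corpus: 250 tiles at 128 px with exact ground
#    truth (200 train / 50 held out)
spec <- orchard_spec(image_size = 128, spacing = 14, jitter = 0.25,
                     crown_radius = c(3, 5), tree_count = c(12, 45),
                     distractor_count = 2, seed = 1)
generate_dataset(spec, 250, c(train = 0.8, test = 0.2), "orchards")

# 2. a small model and a short training run (a few minutes on one core)
cfg <- model_config(input_size = 128, embed_dim = 16,
                    num_heads = c(2, 2, 2, 2), window_size = 4)
fit <- train_swintunet(swintunet(cfg, seed = 2), "orchards",
                       train_config(learning_rate = 1e-2, epochs = 6,
                                    val_every = 2, seed = 3),
                       val_data = "orchards")
#> epoch   1  loss 3.325e-01  lr 1.0e-02
#> epoch   2  loss 3.177e-01  lr 1.0e-02  val EE 21.0%
#> epoch   3  loss 1.698e-01  lr 1.0e-02
#> epoch   4  loss 1.204e-01  lr 1.0e-02  val EE 6.5%
#> epoch   5  loss 7.542e-02  lr 1.0e-03
#> epoch   6  loss 4.964e-02  lr 1.0e-03  val EE 7.2%

# 3. inspect one held-out tile (the test split is tiles 201-250)
img <- read_orchard_image("orchards/orchard_0201.png")
dmap <- swintunet_forward(img, fit$model)
sum(dmap)               # integral of the density map ≈ number of trees
#> [1] 36.5791
predict_count(img, fit$model)   # rounded count; the tile truly has 34
#> [1] 37

# 4. detection-style evaluation on the 50 held-out tiles
ann <- read_annotations("orchards/annotations.csv")
man <- jsonlite::fromJSON("orchards/manifest.json")
test_files <- unlist(man$splits$test)
preds <- sapply(test_files, function(f)
  list(swintunet_forward(read_orchard_image(file.path("orchards", f)),
                         fit$model)))
evaluate(preds, ann[ann$image %in% test_files, ], radius = 4)$pooled
#> counts: NA=1423 NE=1516 missed=68 false=327
#> OA 106.54%  OER 4.8%  CER 22.98%  EE 6.54%
```

The six-epoch model recovers the pooled count to within ~7% and localises
95% of the trees; false detections (CER) are its weak spot at this budget
— peaks split on large crowns — and shrink with longer training. The
per-epoch `loss` is the optimisation loss on density-scale-multiplied
maps (see the vignette); validation EE is tracked every second epoch and
the best parameters are restored at the end.

A thin command-line wrapper over the same functions ships at
`inst/cli/swincount` with subcommands `simulate`, `train` and `evaluate`.

## Scope and caveats

The synthetic generator emulates the *structure* of orchard tiles (crown
blobs with shadows, regular to clustered plantings, distractors), not
their radiometry; results on it demonstrate that the pipeline learns to
count, not field accuracy. Training here is single-image SGD on CPU,
sized for desk-scale experiments; the default 224 px / C = 96
configuration (~41M parameters) is provided and shape-tested but is
intended for substantially longer runs.
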