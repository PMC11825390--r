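---
title: "Quantifying fungal colony color against a reference chart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fungal colony color against a reference chart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycocolor)
```

## The problem

Mycologists describe colony color as a taxonomic character, classically by
visual comparison against a printed chart of named colors (Rayner-style
charts carry on the order of a thousand names, each tied to a hue group
and, through the hue, to the pigment chemistry typical of fungi of that
color). Visual matching is subjective and the charts themselves are rare
and fade. `mycocolor` computes the chart match from a photograph instead.
The inputs are (i) a PNG/JPEG of the specimen with the background either
transparent or filled with a bright-green key color, and (ii) a reference
table with one row per named color: CIELAB coordinates, sRGB coordinates,
a hue group, and associated pigment classes.

## The procedure and its assumptions

**Masking.** A pixel is background iff its alpha is below `alpha_cutoff`
(default 0.5) or all three sRGB channels fall inside the chroma-key
interval, by default lower `(0, 0.55, 0)`, upper `(0.24, 1, 0.24)`. The
target key color is pure green `(0, 1, 0)`; an exact-match mask would be
useless on photographs, so the default is an interval around bright green,
wide enough for compression artifacts yet excluding the yellow-greens real
colonies show. Both bounds are plain arguments — images keyed on another
color, or already masked, just need different bounds. The assumption is
that someone has removed the true background; the package does not
segment.

**Binning.** Foreground pixels are mapped to the working space — CIELAB
via the D65 conversion below, or sRGB as stored — and tallied on a fixed
grid of `bins_per_channel = 2` intervals per channel, 8 boxes in total.
The channel ranges are fixed properties of the space (L\* in [0, 100],
a\* and b\* in [−100, 100], sRGB channels in [0, 1]), so bin boundaries
and centers never depend on the image: empty bins always print the same
centers (L\* 25/75, a\*, b\* ±50). Intervals are half-open `[lo, hi)` with
the last bin closed; a coordinate exactly on an interior boundary (L\* =
50, say) goes to the upper bin. This tie rule is a convention — the
alternative is equally defensible — but it must be fixed for determinism,
and the closed top keeps channel value 1.0 inside the grid. Conversion
output slightly outside the nominal a\*/b\* range (possible for extreme
chroma) stays in the edge bins rather than being dropped. Bin index is
`1 + i1 + 2*i2 + 4*i3` over the 0-based per-channel indices, first channel
fastest; with two bins per channel a bright yellow (high L\*, a\* < 0,
b\* > 0) therefore lands in row 6. Occupied bins report the per-channel
*mean* of their member pixels (computed in the working space itself, not
back-converted from the other space); empty bins report their centers with
proportion 0. Proportions are exact pixel fractions and are rounded (3
decimals) only when a table is printed or serialized.

**Color conversion.** sRGB to CIELAB follows the standard CIE pipeline:
inverse sRGB companding, the sRGB primary matrix to XYZ, then the
piecewise cube-root transform against the D65 2° white point
(0.95047, 1, 1.08883), with the threshold (6/29)³. Two numerical choices
matter. First, the published 7-digit matrix constants map RGB white about
1e−7 away from the white point, which would give neutral grays a\*, b\* on
the order of 1e−5; the matrix rows are normalized so white maps exactly to
the white point and neutrals are exactly neutral. Second, L\*/a\*/b\* are
*never* clamped to the nominal ±100 display range: clamping would corrupt
distances near the gamut edge. The inverse conversion clips out-of-gamut
results channel-wise to [0, 1] for display and flags the affected rows
(`attr(, "clipped")`) instead of erroring, so chart swatches can always be
rendered. Round trips on in-gamut colors are exact to better than 1e−6
per channel.

**Matching.** Each bin representative is matched to the chart entry
minimizing the chosen distance; ties break to the earliest chart row,
which is why table row order is preserved from the source file. Euclidean
distance is the default. The chi-square alternative is the symmetric
histogram form Σ(xᵢ−yᵢ)²/(xᵢ+yᵢ) applied to the coordinate triple, with a
term set to 0 when its denominator is 0. Chi-square presumes non-negative
coordinates; on CIELAB the a\*/b\* denominators can be negative, making
the "distance" negative or unstable. This is preserved deliberately — the
argmin is still taken — because the metric/space mismatch is a real
property of the method worth exposing, not a bug to patch: on the
well-separated fixture geometry in sRGB both metrics agree, while on
CIELAB chi-square is unreliable by construction.

**Collapsing to one hue.** For validation, the 8-row result must become
one predicted hue per image. The default rule takes the hue group of the
highest-proportion bin (earliest bin on ties); a proportion-weighted vote
over hues is available (`predict_hue(method = "weighted")`). Compound
chart hues collapse to their first component for 5-category scoring
("purple-blue" → purple, "blue-green" → blue, "yellow-red" → yellow,
"green-yellow" → green); the mapping is overridable per label because
chart vocabularies differ and no single deduction rule is canonical.

## Agreement statistics

`build_confusion(expected, predicted)` tallies the multiclass matrix with
rows = expected (the published description) and columns = predicted (the
pipeline). Per-category accuracy is the one-vs-rest collapse
(TP+TN)/(TP+TN+FP+FN); Cohen's kappa is (p₀−pₑ)/(1−pₑ) with pₑ from the
margins. `replicate_summary()` reports mean ± sample (n−1) standard
deviation across repeated runs; since this pipeline has no sampling step,
replicate sd is 0 by construction, and the 5-replicate determinism check
in the test suite asserts exactly that. `interpret_kappa()` uses the
Landis–Koch bands by default (0.61–0.80 "substantial"); published reports
sometimes band differently (e.g. calling κ ≈ 0.65 "moderate"), so the
band edges and labels are arguments rather than constants.

## What the synthetic fixtures emulate — and what they do not

The bundled 16-entry chart (`fixture_lookup()`) places one entry exactly
at each CIELAB bin center and one at each sRGB bin center, with hues
spanning the five scoring categories plus compound groups and pigments
spanning the classic classes. Entries at bin centers make nearest-neighbor
results exactly predictable, which is what unit tests need; the names are
synthetic, not Rayner's (the real chart is copyrighted and must be
supplied by the user as a CSV).

`make_swatch_image()` renders flat-color swatches on a chroma-key
background, optionally with i.i.d. Gaussian channel noise (clipped to
[0, 1]), and `make_labeled_dataset()` samples chart colors into a labelled
image set. By default datasets draw from the 8 sRGB-bin-center entries,
whose stored LAB and RGB coordinates are exact inverses, so a zero-noise
dataset is recovered with κ = 1 in either space. Test-suite problem sizes
are 16×16 swatches, 50 images per condition, noise sd swept over
{0, 0.02, 0.08, 0.2}.

Two honest caveats. First, PNG pixels are 8-bit, so a swatch at channel
value 0.75 is stored as 191/255; exact-zero match distances hold for
direct coordinate queries but image-derived representatives sit within one
quantization step of the chart color. Second, because bin representatives
are means over hundreds of pixels, zero-mean channel noise largely cancels
— at every tested noise level recovery stayed at κ = 1, so the
noise-robustness test asserts monotone non-increase of κ rather than
strict decay. Flat noisy swatches exercise bin boundaries and matching
robustness; they do not emulate shadows, glare, uneven lighting, or
multi-colored colonies, so passing them says nothing about those
real-photograph effects (for inconsistently lit photographs the CIELAB
space, which separates lightness from chroma, is the recommended choice).

## Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `space` | `"lab"` | working space for binning and matching (`"rgb"` links lightness with intensity; best for consistent lighting) |
| `metric` | `"euclidean"` | match distance; `"chisq"` is ill-suited to CIELAB (see above) |
| `bins_per_channel` | 2 | histogram resolution per channel (8 boxes) |
| `bounds` | green interval above | chroma-key background window, sRGB units |
| `alpha_cutoff` | 0.5 | opacity below which a pixel is background |
| `noise_sd` (fixtures) | 0 | per-channel Gaussian sd of synthetic swatches |

## Limitations

- The package consumes precomputed LAB/RGB chart columns; it does not
  parse Munsell notations.
- No automatic background segmentation; masking is interval- or
  alpha-based only.
- Fixed-grid binning (no clustering); with 2 bins per channel, colors
  straddling a boundary split across bins, and the representative of a
  wide bin can sit far from every member pixel.
- Achromatic specimens are sensitive to display/lighting conditions of the
  source photograph; dark colors tend to match dark bluish chart entries
  rather than true black.
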