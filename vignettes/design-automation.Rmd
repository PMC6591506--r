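---
title: "Modelling continuous-flow microfluidic devices as component-connection netlists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling continuous-flow microfluidic devices as component-connection netlists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfda)
```

## The model

A continuous-flow lab-on-chip device is represented here the way EDA
tools represent a circuit: not as drawings, but as a netlist. The
`mf_device` container holds

* **functional layers**, always created as FLOW/CONTROL pairs per level.
  Flow layers carry the working fluid; control layers carry the
  pressurised channels that actuate membrane valves. The pairing is
  structural — a valve placed on `control_0` can only be mapped onto a
  channel of `flow_0` — which keeps multilayer (mLSI-style) designs
  well-formed by construction;
* **components**: placed instances of library entities with parameter
  values, a position (micrometres, x right, y up, the position being the
  geometric centre), a CCW rotation, and named ports. Centre-based
  positioning is what makes valve alignment a pure perpendicular
  projection;
* **connections**: channels with an explicit waypoint polyline, one
  source terminal and one or more sink terminals. A *channel element* is
  one straight segment of that polyline; a path of *k* points
  contributes *k − 1* elements. This element count is the unit used both
  by the design statistics and by the effort model's CHANNEL term;
* a **valve map**: key-value pairs from valve component ids to the
  connection each valve pinches. Mapping a valve moves it to the nearest
  point on the channel polyline (ties between equidistant segments
  resolve to the earliest segment in path order) and sets its rotation
  perpendicular to the local channel direction. A level-spanning
  VALVE3D additionally splits the mapped connection into two channels
  that meet at the seat; a plain VALVE only aligns, since only the 3D
  variant physically interrupts the flow channel. Re-mapping an already
  aligned valve is a no-op, so the operation is idempotent.

`validate_device()` turns every structural invariant into a report row
(referential closure, parameter ranges, path/port coincidence within a
snap tolerance of 1e-6 um, valve-map layer pairing). Placing a
flow-functional entity on a control layer is deliberately a *warning*,
not an error: the geometry is manufacturable, merely suspicious.

## Parametric geometry

Library geometry is procedural and chosen to be the simplest
axis-aligned construction with a closed-form area, which is what makes
the geometric tests exact rather than approximate:

* the serpentine **MIXER** with `X = numberOfBends` consists of `2X + 1`
  horizontal bars (`bendLength × channelWidth`) and `2X` vertical bars
  (`channelWidth × bendSpacing`) meeting flush, so its union area is
  exactly `(2X+1)·l·w + 2X·s·w`;
* the **MUX** is a full binary distribution tree with `outputs = 2^k`
  leaf channels (anything else is rejected);
* circles (PORT, VALVE3D membrane) render as 32-gons whose vertex radius
  is inflated by `sqrt((2π/n)/sin(2π/n))` so the polygon area equals
  `πr²` exactly; the true centre/radius is kept alongside for drill
  export. The resolution is registry-configurable.

Default parameter values (e.g. `channelWidth` 400 um, `portRadius`
700 um, `height` 100 um) live in `inst/extdata/entity_registry.json`,
are deliberately registry configuration rather than model constants, and
can be replaced wholesale with `load_entity_registry()`.

Custom entities imported from DXF carry no parametric metadata, so their
only parameters are `height` and a uniform `scale`. DXF inference chains
endpoint-adjacent primitives (endpoints merged within a snap tolerance
defaulting to 1e-6 of the drawing's bounding-box diagonal, a scale-free
choice that tolerates CAD rounding), discretizes arcs, and nests rings
into holes by even-odd containment; open chains are reported, never
silently closed. Overlapping closed shapes are kept separate — unioning
is the manufacturing stage's job.

## Manufacturing layers

Each entity carries a design-for-manufacturing class: **XY** (in-plane
feature milled to one depth), **Z** (through-hole: PORT), **XYZ**
(level-spanning: VALVE3D), **EDGE** (device outline). The 2.5D generator
partitions XY features by (functional layer, height) — heights compared
after rounding to 0.1 um to avoid float-split groups — unions each
group's polygons (Clipper, at a fixed 1e-6 um resolution so flush joints
stay exact), collects each functional layer's Z features into one drill
layer (exported as true circles), and emits the outline as the bounding
box plus a configurable margin when no explicit outline component
exists. The per-entity class assignment is registry-overridable; flow-
and control-layer drills are kept in separate files.

## The effort model

Effort, measured in user *actions*, decomposes component creation into
drawing and parameterization:

\[
E_{Design} = C_{Base} \, f_{Procedural}(X), \qquad
E_{Parameterization} = C_{Identification} + N_{Params}(C_{Constraint} + C_{Value}),
\]

with \(E_{Primitive}\) their sum and the device total the sum over
elements. \(f_{Procedural}\) encodes how manual drawing difficulty
scales with the size parameter: constant, linear (MIXER in its bend
count) or polynomial (MUX in its fan-out). The shipped CAD-mode registry
uses the published mixer calibration \(C_{Base} = 6\),
\(C_{Identification} = 20\), \(C_{Value} = 4\), identity \(f\); the pair
\((N_{Params}, C_{Constraint}) = (5, 0)\) is a documented calibration
choice — 5 matches the mixer's parameter count in this library and 0
completes the 88-action total for the 8-bend mixer. All other entity
rows are this package's own calibration, overridable via
`effort_constants(path)`.

Two open choices were resolved as follows. TOOL mode (drafting inside a
parametric design environment rather than a CAD tool) is modelled as one
placement action plus \(C_{Value}\) per parameter the user actually
edits away from the defaults; the package asserts only the inequality
TOOL < CAD, not a TOOL-mode magnitude. Connections contribute through a
CHANNEL pseudo-entity, linear in the channel-element count, because
element counts are how design scale is measured here; the contribution
is toggleable (`include_connections`) since published totals do not
always state whether routing effort is included.

## Hydraulic simulation

The flow network is the electrical-equivalent model: one node per
component (an ideal junction merging its ports — a zero-resistance merge
rather than a zero-ohm edge, preserving the solver's R > 0 invariant),
one node per interior path vertex, one resistor per channel element with

\[ R = \frac{12 \mu L}{w h^3 (1 - 0.63\, h/w)}, \]

the low-aspect rectangular-duct approximation, symmetric in \(w, h\) by
swapping and valid for aspect ratios \(h/w \le 1\) (the swap keeps the
correction factor in its validity range; strongly square ducts incur a
few percent of model error, which is inherent to the approximation, not
to the solver). The MIXER gets an interior resistor of its unrolled
serpentine centreline length; other interior models can be added per
entity. Valves are open in the steady state; a closed valve removes its
mapped connection's edges. The linear system is a sparse direct nodal
solve — no iteration, no randomness — with pressure boundaries
eliminated and flow boundaries injected; floating subnetworks are
reported as errors listing their nodes, and the worst Kirchhoff
imbalance is returned with the solution.

## Synthetic devices and what the tests show

`random_device()` draws a seeded netlist: entities by weight mix,
grid placement (10 mm pitch, integer coordinates so interchange
round-trips are bit-stable), a random spanning tree plus
density-proportional extra Manhattan channels, and valves mapped onto
random flow channels. The generator emulates the *structure* of real
designs — mixed entity types, multi-height features, valve/channel
relations — at sizes of a few dozen components. It does not emulate
real routing congestion, multi-level (more than one flow/control pair)
stacks, or geometrically meaningful channel lengths, so passing tests
demonstrate model, format and solver correctness, not fluidic
performance of any physical chip. The scripted
`build_daridon_style_fixture()` is a *style* reconstruction of a
published single-cell-trap workflow (port arrays, imported custom trap,
chambers, mapped valves, control plumbing); it makes no claim to the
original's component counts. The bundled trap drawing is synthetic
(`cell_trap_synthetic.dxf`).

Problem sizes used by the checks — 100 seeded devices of up to 50
components for serialization and effort identities, 50 random resistor
networks of up to 40 edges plus 10 ladder networks for the solver, bend
counts 1–20 for mixer geometry — were chosen so each property is
exercised across its parameter range while the whole suite stays
interactive (well under a minute).

## Numerical choices and limitations

* Interchange floats are canonicalized at 6 decimal places of a
  micrometre; component/connection maps serialize in id order, making
  output byte-stable under read/write cycles.
* Device equality is defined on the canonical form
  (`canonicalize_device()`): map storage order is not part of the
  design.
* Polygon clipping resolution is fixed at 1e-6 um; simplicity checks use
  an O(n²) proper-crossing test, adequate for the small rings produced
  here.
* Auto-placement is a deliberately naive row-major grid (default: one
  row) with Manhattan re-routing — it is plumbing for HDL import, not a
  router; automated routing is out of scope.
* The MINT-style importer accepts the documented subset only (DEVICE /
  LAYER blocks, component, CHANNEL and VALVE-on-channel statements), and
  the ParchMINT writer emits this package's own schema version with the
  valve map, heights and id counters as superset extensions.
* The effort constants beyond the mixer row, and the per-entity DFM
  assignments, are calibration configuration, not measured values.
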