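# Default Human Influence Index layer parameterization: 16 human land-use
# inputs with site impact score (intactness at distance 0; lower = greater
# impact), distance of influence (m; distance at which intactness reaches
# 1.0) and distance-decay family. Edit site_impact / distance_m / decay to
# re-parameterize without code changes; source_path points at a GeoJSON (or
# presence raster for raster_mask layers) when running on real data.
layers:
  - name: primitive_roads
    category: transportation
    geometry_kind: line
    site_impact: 0.75
    distance_m: 500
    decay: linear
    source_path: null
  - name: local_roads
    category: transportation
    geometry_kind: line
    site_impact: 0.3
    distance_m: 1500
    decay: logistic
    source_path: null
  - name: major_highways
    category: transportation
    geometry_kind: line
    site_impact: 0.015
    distance_m: 4000
    decay: logistic
    source_path: null
  - name: low_density_development
    category: urban_industrial
    geometry_kind: polygon
    site_impact: 0.6
    distance_m: 1000
    decay: logistic
    source_path: null
  - name: medium_density_development
    category: urban_industrial
    geometry_kind: polygon
    site_impact: 0.35
    distance_m: 2000
    decay: logistic
    source_path: null
  - name: high_density_development
    category: urban_industrial
    geometry_kind: polygon
    site_impact: 0.015
    distance_m: 4000
    decay: logistic
    source_path: null
  - name: communication_towers
    category: urban_industrial
    geometry_kind: point
    site_impact: 0.6
    distance_m: 200
    decay: linear
    source_path: null
  - name: powerlines
    category: urban_industrial
    geometry_kind: line
    site_impact: 0.6
    distance_m: 200
    decay: linear
    source_path: null
  - name: mines_and_well_pads
    category: urban_industrial
    geometry_kind: point
    site_impact: 0.2
    distance_m: 1000
    decay: logistic
    source_path: null
  - name: urban_polygons
    category: urban_industrial
    geometry_kind: polygon
    site_impact: 0.015
    distance_m: 4000
    decay: logistic
    source_path: null
  - name: high_impervious_surfaces
    category: urban_industrial
    geometry_kind: raster_mask
    site_impact: 0.3
    distance_m: 1000
    decay: logistic
    source_path: null
  - name: low_agriculture_and_invasives
    category: managed_landcover
    geometry_kind: polygon
    site_impact: 0.7
    distance_m: 500
    decay: linear
    source_path: null
  - name: pasture
    category: managed_landcover
    geometry_kind: polygon
    site_impact: 0.7
    distance_m: 500
    decay: linear
    source_path: null
  - name: grazing_allotments
    category: managed_landcover
    geometry_kind: polygon
    site_impact: 0.7
    distance_m: 500
    decay: linear
    source_path: null
  - name: introduced_vegetation
    category: managed_landcover
    geometry_kind: polygon
    site_impact: 0.6
    distance_m: 500
    decay: linear
    source_path: null
  - name: cultivated_agriculture
    category: managed_landcover
    geometry_kind: polygon
    site_impact: 0.35
    distance_m: 2000
    decay: linear
    source_path: null
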