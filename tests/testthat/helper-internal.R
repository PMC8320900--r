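# Internal helpers exercised directly by the suite.
polygons_overlap <- acuflow:::polygons_overlap
polygon_edge_lengths <- acuflow:::polygon_edge_lengths
points_in_polygon <- acuflow:::points_in_polygon
clip_halfplane <- acuflow:::clip_halfplane
erode_convex_polygon <- acuflow:::erode_convex_polygon
polygon_centroid <- acuflow:::polygon_centroid
voronoi_mesh <- acuflow:::voronoi_mesh
scale_diameters <- acuflow:::scale_diameters
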