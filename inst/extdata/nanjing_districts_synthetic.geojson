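{
  "type": "FeatureCollection",
  "features": [
    {
      "type": "Feature",
      "properties": {
        "district": "Liuhe",
        "area_km2": 1485,
        "builtup_fraction": 0.1,
        "water_fraction": 0.12,
        "geometry_note": "synthetic grid cell, not a survey boundary"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [
              [118.6, 32.1],
              [118.85, 32.1],
              [118.85, 32.35],
              [118.6, 32.35],
              [118.6, 32.1]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "district": "Pukou",
        "area_km2": 913,
        "builtup_fraction": 0.12,
        "water_fraction": 0.12,
        "geometry_note": "synthetic grid cell, not a survey boundary"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [
              [118.35, 32.1],
              [118.6, 32.1],
              [118.6, 32.35],
              [118.35, 32.35],
              [118.35, 32.1]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "district": "Xiaguan",
        "area_km2": 31,
        "builtup_fraction": 0.7,
        "water_fraction": 0.25,
        "geometry_note": "synthetic grid cell, not a survey boundary"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [
              [118.6, 31.85],
              [118.85, 31.85],
              [118.85, 32.1],
              [118.6, 32.1],
              [118.6, 31.85]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "district": "Qixia",
        "area_km2": 395,
        "builtup_fraction": 0.25,
        "water_fraction": 0.15,
        "geometry_note": "synthetic grid cell, not a survey boundary"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [
              [118.85, 31.85],
              [119.1, 31.85],
              [119.1, 32.1],
              [118.85, 32.1],
              [118.85, 31.85]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "district": "Jianye",
        "area_km2": 83,
        "builtup_fraction": 0.55,
        "water_fraction": 0.15,
        "geometry_note": "synthetic grid cell, not a survey boundary"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [
              [118.35, 31.6],
              [118.6, 31.6],
              [118.6, 31.85],
              [118.35, 31.85],
              [118.35, 31.6]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "district": "Gulou",
        "area_km2": 25,
        "builtup_fraction": 0.8,
        "water_fraction": 0.08,
        "geometry_note": "synthetic grid cell, not a survey boundary"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [
              [118.6, 31.6],
              [118.85, 31.6],
              [118.85, 31.85],
              [118.6, 31.85],
              [118.6, 31.6]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "district": "Xuanwu",
        "area_km2": 81,
        "builtup_fraction": 0.6,
        "water_fraction": 0.1,
        "geometry_note": "synthetic grid cell, not a survey boundary"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [
              [118.85, 31.6],
              [119.1, 31.6],
              [119.1, 31.85],
              [118.85, 31.85],
              [118.85, 31.6]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "district": "Yuhuatai",
        "area_km2": 132,
        "builtup_fraction": 0.4,
        "water_fraction": 0.1,
        "geometry_note": "synthetic grid cell, not a survey boundary"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [
              [118.35, 31.35],
              [118.6, 31.35],
              [118.6, 31.6],
              [118.35, 31.6],
              [118.35, 31.35]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "district": "Qinhuai",
        "area_km2": 23,
        "builtup_fraction": 0.8,
        "water_fraction": 0.08,
        "geometry_note": "synthetic grid cell, not a survey boundary"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [
              [118.6, 31.35],
              [118.85, 31.35],
              [118.85, 31.6],
              [118.6, 31.6],
              [118.6, 31.35]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "district": "Baixia",
        "area_km2": 27,
        "builtup_fraction": 0.8,
        "water_fraction": 0.05,
        "geometry_note": "synthetic grid cell, not a survey boundary"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [
              [118.85, 31.35],
              [119.1, 31.35],
              [119.1, 31.6],
              [118.85, 31.6],
              [118.85, 31.35]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "district": "Jiangning",
        "area_km2": 1573,
        "builtup_fraction": 0.1,
        "water_fraction": 0.1,
        "geometry_note": "synthetic grid cell, not a survey boundary"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [
              [118.6, 31.1],
              [118.85, 31.1],
              [118.85, 31.35],
              [118.6, 31.35],
              [118.6, 31.1]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "district": "Lishui",
        "area_km2": 1067,
        "builtup_fraction": 0.08,
        "water_fraction": 0.1,
        "geometry_note": "synthetic grid cell, not a survey boundary"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [
              [118.85, 31.1],
              [119.1, 31.1],
              [119.1, 31.35],
              [118.85, 31.35],
              [118.85, 31.1]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "district": "Gaochun",
        "area_km2": 802,
        "builtup_fraction": 0.08,
        "water_fraction": 0.15,
        "geometry_note": "synthetic grid cell, not a survey boundary"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [
              [118.85, 30.85],
              [119.1, 30.85],
              [119.1, 31.1],
              [118.85, 31.1],
              [118.85, 30.85]
            ]
          ]
        ]
      }
    }
  ]
}
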