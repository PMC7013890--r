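{
  "description": "Category codings for the 17 candidate factors of the Shenzhen traffic-accident severity analysis.",
  "factors": [
    {
      "name": "zones",
      "group": "Geographical Region",
      "categories": [
        {"code": 1, "label": "City Center zone"},
        {"code": 2, "label": "Western coastal zone"},
        {"code": 3, "label": "Midland zone"},
        {"code": 4, "label": "Eastern zone"},
        {"code": 5, "label": "Eastern coastal zone"}
      ]
    },
    {
      "name": "seasons",
      "group": "Time of Occurrence",
      "categories": [
        {"code": 1, "label": "Spring (March-May)"},
        {"code": 2, "label": "Summer (June-September)"},
        {"code": 3, "label": "Autumn (October-November)"},
        {"code": 4, "label": "Winter (December-February)"}
      ]
    },
    {
      "name": "day_of_week",
      "group": "Time of Occurrence",
      "categories": [
        {"code": 1, "label": "Monday"},
        {"code": 2, "label": "Tuesday"},
        {"code": 3, "label": "Wednesday"},
        {"code": 4, "label": "Thursday"},
        {"code": 5, "label": "Friday"},
        {"code": 6, "label": "Saturday"},
        {"code": 7, "label": "Sunday"}
      ]
    },
    {
      "name": "time_interval",
      "group": "Time of Occurrence",
      "categories": [
        {"code": 1, "label": "00:00-06:59 (midnight to dawn)"},
        {"code": 2, "label": "07:00-08:59 (morning rush hours)"},
        {"code": 3, "label": "09:00-11:59 (morning working hours)"},
        {"code": 4, "label": "12:00-17:29 (afternoon working hours)"},
        {"code": 5, "label": "17:30-19:29 (afternoon rushing hours)"},
        {"code": 6, "label": "19:30-23:59 (nighttime)"}
      ]
    },
    {
      "name": "road_type",
      "group": "Road Factors",
      "categories": [
        {"code": 1, "label": "Highway"},
        {"code": 2, "label": "Urban Expressway"},
        {"code": 3, "label": "First-class highway"},
        {"code": 4, "label": "Second-class highway"},
        {"code": 5, "label": "Third-class highway"},
        {"code": 6, "label": "Fourth-class highway"},
        {"code": 7, "label": "Substandard road"},
        {"code": 8, "label": "Branch urban road"},
        {"code": 9, "label": "Road in public parking"},
        {"code": 10, "label": "Road in public square"},
        {"code": 11, "label": "Road in community"},
        {"code": 12, "label": "Other road"}
      ]
    },
    {
      "name": "road_line_style",
      "group": "Road Factors",
      "categories": [
        {"code": 1, "label": "Straight"},
        {"code": 2, "label": "General curve"},
        {"code": 3, "label": "General slope"},
        {"code": 4, "label": "General curve and general slope"},
        {"code": 5, "label": "Steep slope"},
        {"code": 6, "label": "Sharp curve"},
        {"code": 7, "label": "General curve and steep slope"},
        {"code": 8, "label": "General slope and sharp curve"},
        {"code": 9, "label": "Sharp curve and steep slope"}
      ]
    },
    {
      "name": "road_section_type",
      "group": "Road Factors",
      "categories": [
        {"code": 1, "label": "Ordinary section"},
        {"code": 2, "label": "Plane intersection"},
        {"code": 3, "label": "Bridge"},
        {"code": 4, "label": "Access"},
        {"code": 5, "label": "Internal section"},
        {"code": 6, "label": "Elevated section"},
        {"code": 7, "label": "Ramp"},
        {"code": 8, "label": "Tunnel"},
        {"code": 9, "label": "Narrow section"}
      ]
    },
    {
      "name": "pavement_material",
      "group": "Road Factors",
      "categories": [
        {"code": 1, "label": "Asphalt concrete"},
        {"code": 2, "label": "Cement concrete"},
        {"code": 3, "label": "Sand"},
        {"code": 4, "label": "Soil"},
        {"code": 5, "label": "Others"}
      ]
    },
    {
      "name": "pavement_condition",
      "group": "Road Factors",
      "categories": [
        {"code": 1, "label": "Good"},
        {"code": 2, "label": "Under construction"},
        {"code": 3, "label": "Convex-concave"},
        {"code": 4, "label": "Others"}
      ]
    },
    {
      "name": "roadside_protection",
      "group": "Road Factors",
      "categories": [
        {"code": 1, "label": "Green belt"},
        {"code": 2, "label": "Border tree"},
        {"code": 3, "label": "Concrete guardrail"},
        {"code": 4, "label": "Protective Pier (column)"},
        {"code": 5, "label": "Metal guardrail"},
        {"code": 6, "label": "Corrugated beam guardrail"},
        {"code": 7, "label": "No protection"}
      ]
    },
    {
      "name": "traffic_sign",
      "group": "Management Status",
      "categories": [
        {"code": 0, "label": "Bad or no"},
        {"code": 1, "label": "Good"}
      ]
    },
    {
      "name": "lighting_condition",
      "group": "Management Status",
      "categories": [
        {"code": 1, "label": "Daytime"},
        {"code": 2, "label": "Street lighting at night"},
        {"code": 3, "label": "No street lighting at night"}
      ]
    },
    {
      "name": "weather",
      "group": "Environment Condition",
      "categories": [
        {"code": 1, "label": "Sunny"},
        {"code": 2, "label": "Cloudy"},
        {"code": 3, "label": "Rainy"},
        {"code": 4, "label": "Others"}
      ]
    },
    {
      "name": "topography",
      "group": "Environment Condition",
      "categories": [
        {"code": 1, "label": "Plain"},
        {"code": 2, "label": "Hill"},
        {"code": 3, "label": "Mountain"}
      ]
    },
    {
      "name": "primary_cause",
      "group": "Traffic Violations",
      "categories": [
        {"code": 1, "label": "Drunk driving"},
        {"code": 2, "label": "Driving under the influence of alcohol"},
        {"code": 3, "label": "Speeding over 50%"},
        {"code": 4, "label": "Speeding below 50%"},
        {"code": 5, "label": "Overloading"},
        {"code": 6, "label": "Backing and wrong-way driving on highway"},
        {"code": 7, "label": "License violation"},
        {"code": 8, "label": "Illegal overtaking"},
        {"code": 9, "label": "Traffic signal violation"},
        {"code": 10, "label": "Traffic sign violation"},
        {"code": 11, "label": "Wrong-way driving, not on highway"},
        {"code": 12, "label": "Illegal road occupying"},
        {"code": 13, "label": "Illegal backing"},
        {"code": 14, "label": "Failure to give way properly"},
        {"code": 15, "label": "Illegal meeting"},
        {"code": 16, "label": "Helmet violation"},
        {"code": 17, "label": "Illegal entering onto highway"},
        {"code": 18, "label": "Vehicle defect"},
        {"code": 19, "label": "Other violations"},
        {"code": 20, "label": "Road facilities hazard"},
        {"code": 21, "label": "Other non-illegal fault"}
      ]
    },
    {
      "name": "whether_illegal",
      "group": "Traffic Violations",
      "categories": [
        {"code": 0, "label": "Legal fault"},
        {"code": 1, "label": "Illegal fault"}
      ]
    },
    {
      "name": "responsible_party",
      "group": "Traffic Violations",
      "categories": [
        {"code": 1, "label": "Pedestrians"},
        {"code": 2, "label": "Non-motorized vehicles"},
        {"code": 3, "label": "Minibuses"},
        {"code": 4, "label": "Large and medium buses"},
        {"code": 5, "label": "Light trucks"},
        {"code": 6, "label": "Heavy trucks"},
        {"code": 7, "label": "Motorcycles"},
        {"code": 8, "label": "Other motor vehicles"},
        {"code": 9, "label": "Traffic management authority"},
        {"code": 10, "label": "Others"}
      ]
    }
  ]
}
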