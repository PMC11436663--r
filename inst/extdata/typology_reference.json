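{
  "archetypes": [
    {
      "id": "A",
      "label": "Primary forests",
      "cells": [["n5", "passive"], ["n6", "passive"], ["n7", "passive"]]
    },
    {
      "id": "B",
      "label": "Newly untouched forest",
      "cells": [["n4", "passive"]]
    },
    {
      "id": "C",
      "label": "Specially managed forest under closer-to-nature forestry",
      "cells": [["n3", "low"]]
    },
    {
      "id": "D",
      "label": "Exploited natural forest under closer-to-nature or combined objective forestry",
      "cells": [["n2", "low"], ["n2", "medium"]]
    },
    {
      "id": "E",
      "label": "Plantation-like natural forest under intensive even-aged forestry",
      "cells": [["n1", "high"]]
    },
    {
      "id": "F",
      "label": "Partly natural forest under passive to medium intensity forest management",
      "cells": [["p4", "passive"], ["p4", "low"], ["p4", "medium"]]
    },
    {
      "id": "G",
      "label": "Native plantation under intensive even-aged or short-rotation forestry",
      "cells": [["p3", "high"], ["p3", "intensive"]]
    },
    {
      "id": "H",
      "label": "Exotic plantation under intensive even-aged or short-rotation forestry",
      "cells": [["p2", "high"], ["p2", "intensive"]]
    },
    {
      "id": "I",
      "label": "Exotic self-sown forest under intensive even-aged or short-rotation forestry",
      "cells": [["p1", "high"], ["p1", "intensive"]]
    }
  ]
}
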