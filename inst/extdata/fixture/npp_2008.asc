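ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
245.908  273.97 214.189 191.125 295.335 315.496 273.489 217.447 202.167 217.974 359.112 399.165 228.937 349.452 325.929 257.149
 302.18  299.92 232.091 227.434 294.121 262.586 213.627 203.088 182.522  212.13 270.676 227.537  220.79 356.387 252.172 302.936
325.032 283.746 264.483 296.483 333.399 334.555 259.637 182.663 198.208 272.057 385.635 347.554 401.551 362.775 385.168  402.86
 267.15 272.831 239.103 220.298 322.246 293.179 202.272 205.738 167.137 272.649 315.591 267.176 210.582 312.347 354.362 465.369
255.936 241.983 229.526  219.24 243.042 295.457 235.016 238.327  188.59 262.523 366.391 261.311 181.385  233.55 247.679 369.906
294.758 214.998 195.529 191.909 195.361  224.29  157.23 156.716 157.409 206.129 226.152 240.871 142.531 205.523 160.136 203.914
368.375 381.958 314.106 294.083 279.786 320.036 186.564 183.655 184.629 208.926 207.542 164.539  133.02 172.678  193.88  230.54
277.329 263.699 208.111   203.4 275.419 266.884 188.641 211.899 284.765 240.305 202.196  215.46 178.751 176.852 144.512 159.747
306.638 204.157 236.307 264.926  246.91 252.878 243.512 216.139 243.559 225.403 193.551 237.187 194.302 183.858 172.966 197.891
220.318 222.205 194.525 217.643 213.314 239.474 216.414 152.676 199.375 206.569 135.415 134.356 131.975 152.062 182.826 163.301
165.633 174.524 168.367 173.932 140.648 233.739 229.775 159.171 195.177 291.103 186.412 214.732 173.156 151.103 191.268 117.501
194.611 182.287  266.36 186.812 168.643 203.281 216.919  189.75 216.937 242.756 169.084 244.188 171.704 137.804 208.406 152.234
168.754 158.601 235.291 208.533 236.994 250.605 322.846 279.772 252.729 307.032 281.106 414.804 278.464 237.777 319.494 195.276
157.393  138.42 169.841 168.626 170.652 174.685 203.351  210.58 304.872 327.479 451.445 553.644 488.007 438.485 394.168 223.514
213.098 165.421 207.485 178.393 171.704 166.159 210.897 201.521 346.203 466.278 485.309 724.106  542.59 466.796 599.109 279.064
154.811 180.959 168.257 170.199 211.377 199.301 278.782 379.456 430.945 501.521 607.466 664.835 567.047 437.421 393.469 256.146
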