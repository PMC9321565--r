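ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
250.147 246.059 258.971 190.829 225.276 272.478 238.734 216.083 179.198   192.5 282.612 278.362 285.465 305.967 231.495 326.397
302.116 267.897 211.562 194.571 230.793 255.683 200.606   165.2 187.379 182.229 304.255 298.051 248.645 352.376 294.465   283.2
375.966 241.732 273.708 276.885 256.692 264.792 204.401 206.344 216.249 235.074 330.948 399.527 263.137 437.835 331.573 439.612
256.968 276.098 228.214 204.617 291.591 310.375 213.473 146.299 165.791 253.884 281.711 260.226 250.062 335.115 344.895 377.183
283.167 299.552 227.631  219.03 281.941 262.948 197.957 210.945 249.852 246.049 291.592 260.468 155.506 282.042 264.121 332.199
343.411 212.885 178.356 199.258 209.831 234.739 178.984 157.926 154.766 158.032 204.928 169.172 114.283 247.629 189.075 213.571
 413.39 347.264  272.86 290.716 228.535 306.922 197.096 155.615  184.48 166.608 189.692 149.693  114.31 175.304 197.338 184.768
277.595 253.744 245.453 309.181 268.146 277.843  218.41 260.723 235.239 284.953  201.03 178.107 163.053 167.142 145.825 184.723
312.338 216.515 225.772 235.353 246.228 258.659 205.231 195.616 260.391  240.87 138.479 156.542 160.483 149.712 170.843 182.737
278.963 254.285 215.952 205.173 194.344 229.674 216.167 211.395 218.673 199.951 166.069 140.654 113.378 111.533 167.554 151.912
154.451 181.805 174.187 171.147 154.846 210.859 241.058 195.383 230.347 281.917 186.284 263.694 194.791 161.963  153.58 107.644
173.644 176.835 224.177 221.507 202.854  163.77 287.372 204.526 223.593 294.325 218.251 231.772 203.876 153.587 196.881 118.139
167.039 190.289 224.408 205.143 226.467 273.577 346.261 347.238 412.777 437.433  320.21  403.63 356.318 192.433 273.846 182.327
173.415 151.941 177.087 174.168 163.283 148.954 221.167 281.445 336.188 471.153 470.279 582.912 458.356 375.167 471.794 210.425
183.308 189.046 181.927 174.265 181.409 156.745 243.783 220.282 290.572 479.049 619.626 734.317 687.011 594.624 565.597 282.136
179.509  188.79 160.336  192.79 212.273  216.93 309.422 309.649 375.828 627.227 676.594 826.172 568.787 581.753  501.36 337.787
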