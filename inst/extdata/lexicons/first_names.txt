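Aaron
Abigail
Adam
Alan
Albert
Alice
Amanda
Amber
Amy
Andrea
Andrew
Angela
Ann
Anna
Anthony
April
Arthur
Ashley
Barbara
Benjamin
Beth
Betty
Beverly
Bonnie
Brandon
Brenda
Brian
Bruce
Candy
Carl
Carol
Carolyn
Catherine
Charles
Charlotte
Cheryl
Christina
Christine
Christopher
Cindy
Claire
Connie
Craig
Crystal
Cynthia
Dale
Daniel
Danielle
David
Dawn
Deborah
Debra
Denise
Dennis
Diana
Diane
Don
Donald
Donna
Doris
Dorothy
Douglas
Earl
Edward
Eileen
Elaine
Eleanor
Elizabeth
Ellen
Emily
Emma
Eric
Erin
Esther
Eugene
Evelyn
Faith
Florence
Frances
Frank
Fred
Gail
Gary
George
Gerald
Gladys
Glenn
Gloria
Grace
Gregory
Hannah
Harold
Harry
Heather
Helen
Henry
Hope
Howard
Irene
Jack
Jacob
Jacqueline
James
Jane
Janet
Janice
Jason
Jean
Jeffrey
Jennifer
Jeremy
Jerry
Jessica
Jill
Joan
Joanne
Joe
John
Jonathan
Joseph
Josephine
Joshua
Joyce
Juanita
Judith
Judy
Julia
Julie
Justin
Karen
Katherine
Kathleen
Kathryn
Kathy
Keith
Kelly
Kenneth
Kevin
Kimberly
Kyle
Larry
Laura
Lauren
Lawrence
Leonard
Lillian
Linda
Lisa
Lois
Loretta
Lori
Louise
Lucille
Margaret
Maria
Marie
Marilyn
Marjorie
Mark
Martha
Martin
Marvin
Mary
Matthew
Meg
Megan
Melissa
Michael
Michelle
Mildred
Nancy
Natalie
Nathan
Nicholas
Nicole
Norma
Norman
Olivia
Pamela
Patricia
Patrick
Paul
Paula
Peggy
Peter
Philip
Phyllis
Rachel
Ralph
Randy
Raymond
Rebecca
Regina
Richard
Rita
Robert
Roger
Ronald
Rose
Roy
Russell
Ruth
Ryan
Samantha
Samuel
Sandra
Sarah
Scott
Sean
Sharon
Shirley
Sophia
Stanley
Stephanie
Stephen
Steven
Sunday
Susan
Sylvia
Tammy
Teresa
Terry
Theodore
Theresa
Thomas
Timothy
Tina
Todd
Tracy
Valerie
Victoria
Vincent
Virginia
Walter
Wanda
Wayne
William
Willie
Yvonne
Zachary
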